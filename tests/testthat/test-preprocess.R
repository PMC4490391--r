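test_that("subread filters apply strict-below removal with inclusive bounds", {
  long_ops <- rep("M", 500L)
  ds <- make_dataset(
    make_subread("fail_mapqv", 0L, 0L, long_ops, mapqv = 239L, accuracy = 0.99),
    make_subread("pass_bounds", 0L, 0L, rep("M", 100L), mapqv = 254L,
                 accuracy = 0.80),
    make_subread("fail_acc", 0L, 0L, long_ops, accuracy = 0.79),
    make_subread("fail_len", 0L, 0L, rep("M", 99L), accuracy = 0.99))
  kept <- filter_subreads(ds, preprocess_config())
  expect_equal(unique(kept$events$molecule_id), "pass_bounds")
})

test_that("filtering equals an independent per-subread predicate", {
  set.seed(7)
  subs <- lapply(1:10, function(i)
    make_subread(paste0("m", i), 0L, 0L, rep("M", sample(80:140, 1L)),
                 mapqv = sample(c(200L, 240L, 254L), 1L),
                 accuracy = runif(1, 0.7, 1)))
  ds <- do.call(make_dataset, subs)
  cfg <- preprocess_config()
  kept <- unique(filter_subreads(ds, cfg)$events$molecule_id)
  manual <- vapply(subs, function(s) {
    s$mapqv[1L] >= 240L && s$accuracy[1L] >= 0.80 &&
      sum(s$op != "I") >= 100L
  }, logical(1))
  expect_setequal(kept, vapply(subs, function(s) s$molecule_id[1L],
                               character(1))[manual])
})

test_that("error-adjacent masking drops the documented window", {
  # M M M X M M M with radius 1: IPDs survive at read indices 0,1,5,6
  ds <- make_dataset(make_subread("m", 0L, 0L,
                                  c("M", "M", "M", "X", "M", "M", "M"),
                                  ipd = 1:7))
  masked <- mask_error_adjacent(ds, 1L)
  expect_equal(which(!is.na(masked$events$ipd)), c(1L, 2L, 6L, 7L))
  # an error-free subread is untouched
  clean <- make_dataset(make_subread("m", 0L, 0L, rep("M", 5L), ipd = 1:5))
  expect_equal(mask_error_adjacent(clean, 1L)$events$ipd, as.numeric(1:5))
})

test_that("masking equals brute-force union of error windows and is monotone", {
  set.seed(11)
  for (rep_i in 1:5) {
    n <- sample(20:60, 1L)
    ops <- sample(c("M", "X", "I", "D"), n, replace = TRUE,
                  prob = c(0.85, 0.05, 0.05, 0.05))
    ds <- make_dataset(make_subread("m", 0L, 0L, ops, ipd = seq_len(n)))
    for (r in 0:3) {
      got <- mask_error_adjacent(ds, r)$events
      err_idx <- which(ops != "M")
      windows <- unique(unlist(lapply(err_idx, function(e)
        max(1L, e - r):min(n, e + r))))
      emits <- ops %in% c("M", "X", "I")
      keep <- setdiff(which(emits), windows)
      expect_equal(which(!is.na(got$ipd)), sort(keep))
    }
    kept_r1 <- which(!is.na(mask_error_adjacent(ds, 1L)$events$ipd))
    kept_r2 <- which(!is.na(mask_error_adjacent(ds, 2L)$events$ipd))
    expect_true(all(kept_r2 %in% kept_r1))
  }
})

test_that("edge trimming drops head/tail events and exhausts short subreads", {
  ds25 <- make_dataset(make_subread("m", 0L, 0L, rep("M", 25L)))
  expect_equal(nrow(trim_edges(ds25, 10L, 15L)$events), 0L)
  ds30 <- make_dataset(make_subread("m", 0L, 0L, rep("M", 30L), ipd = 1:30))
  kept <- trim_edges(ds30, 10L, 15L)$events
  expect_equal(kept$ipd, as.numeric(11:15))   # read indices 10..14 (0-based)
  expect_identical(trim_edges(ds30, 0L, 0L)$events, ds30$events)
})

test_that("normalization is a closed-form mean-centred natural log", {
  ds <- make_dataset(make_subread("m", 0L, 0L, rep("M", 3L),
                                  ipd = exp(1:3)))
  obs <- normalize_and_log(ds, preprocess_config())
  expect_equal(obs$log_ipd, c(-1, 0, 1), tolerance = 1e-12)
})

test_that("per-molecule normalized means are zero and scale-invariant", {
  sim <- simulate_dataset(quick_sim(5, n_molecules = 100L))
  obs <- preprocess(sim$dataset)
  mol_means <- obs[, mean(log_ipd), by = molecule_id]$V1
  expect_lt(max(abs(mol_means)), 1e-9)
  expect_gte(uniqueN(obs$molecule_id), 90L)
  # molecule-wise rescaling of raw IPDs leaves observations unchanged
  ds2 <- sim$dataset
  ds2$events <- copy(ds2$events)
  scale_map <- ds2$events[, .(f = runif(1, 0.1, 10)),
                          by = molecule_id]
  ds2$events[scale_map, ipd := ipd * i.f, on = "molecule_id"]
  obs2 <- preprocess(ds2)
  expect_equal(obs2$log_ipd, obs$log_ipd, tolerance = 1e-9)
})

test_that("no observation comes from insertions, deletions or masked bases", {
  sim <- simulate_dataset(quick_sim(6, n_molecules = 20L))
  obs <- preprocess(sim$dataset)
  ev <- sim$dataset$events[op == "M"]
  joined <- ev[obs, on = c("molecule_id", "subread_index", "strand",
                           "ref_pos"), nomatch = NULL]
  expect_equal(nrow(joined), nrow(obs))   # every obs maps to a match event
})

test_that("pipeline equals step-by-step application and counts add up", {
  sim <- simulate_dataset(quick_sim(8, n_molecules = 3L, error_rate = 0))
  cfg <- preprocess_config()
  manual <- normalize_and_log(
    trim_edges(mask_error_adjacent(filter_subreads(sim$dataset, cfg),
                                   cfg$error_mask_radius),
               cfg$head_trim, cfg$tail_trim), cfg)
  piped <- preprocess(sim$dataset, cfg)
  expect_equal(piped, manual)
  # error-free data: one observation per event surviving the edge trim
  sub_len <- sim$dataset$events[, .N, by = .(molecule_id, subread_index)]$N
  expect_equal(nrow(piped), sum(pmax(0L, sub_len - 25L)))
})

test_that("a dataset whose subreads all fail a filter yields nothing", {
  ds <- make_dataset(make_subread("m", 0L, 0L, rep("M", 50L)))
  expect_equal(nrow(preprocess(ds)), 0L)
})
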