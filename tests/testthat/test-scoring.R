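test_that("control lookup stores per-key means and counts", {
  obs <- make_obs(c("w1", "w2"), c(0L, 0L), c(5L, 5L),
                  list(0.2, 0.4), sample_type = "WGA")
  ctrl <- build_control(obs)
  expect_equal(nrow(ctrl), 1L)
  expect_equal(ctrl$mean_log_ipd, 0.3)
  expect_equal(ctrl$n, 2L)
  native <- make_obs("n1", 0L, 5L, list(0.2))
  expect_error(build_control(native), "WGA")
})

test_that("control means equal a brute-force group-by on 1000 observations", {
  set.seed(21)
  n <- 1000L
  obs <- data.table(molecule_id = sample(sprintf("w%02d", 1:20), n, TRUE),
                    subread_index = 0L,
                    strand = sample(0:1, n, TRUE),
                    ref_pos = sample(1:30, n, TRUE),
                    log_ipd = rnorm(n))
  setattr(obs, "sample_type", "WGA")
  ctrl <- build_control(obs)
  brute <- aggregate(log_ipd ~ strand + ref_pos, data = as.data.frame(obs),
                     FUN = mean)
  merged <- merge(as.data.frame(ctrl), brute, by = c("strand", "ref_pos"))
  expect_equal(nrow(merged), nrow(ctrl))
  expect_lt(max(abs(merged$mean_log_ipd - merged$log_ipd)), 1e-12)
})

test_that("SM_SN is the molecule mean minus the control mean", {
  native <- make_obs("mol1", 0L, 10L, list(c(1.0, 1.2, 0.8)))
  ctrl <- build_control(make_obs("w", 0L, 10L, list(0.5),
                                 sample_type = "WGA"))
  sites <- make_sites(10L, 0L)
  sc <- smsn_scores(native, ctrl, sites, min_cov = 1L)
  expect_equal(sc$score, 0.5, tolerance = 1e-12)
  expect_equal(sc$cov_sm, 3L)
  # native identical to the control mean scores zero
  null <- make_obs("mol2", 0L, 10L, list(rep(0.5, 4L)))
  expect_equal(smsn_scores(null, ctrl, sites, min_cov = 1L)$score, 0)
})

test_that("min_cov and missing-control skips are applied and counted", {
  native <- make_obs(c("a", "a", "b"), c(0L, 0L, 0L), c(1L, 2L, 1L),
                     list(c(0.1, 0.2, 0.3), 0.5, c(0.2, 0.4)))
  ctrl <- build_control(make_obs("w", 0L, 1L, list(c(0, 0.2)),
                                 sample_type = "WGA"))
  sites <- make_sites(c(1L, 2L), c(0L, 0L))
  sc <- smsn_scores(native, ctrl, sites, min_cov = 2L)
  # a@2 fails cov, b@1 passes, a@1 passes; site 2 lacks control anyway
  expect_equal(nrow(sc), 2L)
  rep <- attr(sc, "skip_report")
  expect_equal(rep$low_coverage, 1L)
  expect_equal(rep$no_control, 0L)   # the low-cov group is also control-less
})

test_that("Agg_SN pools molecules with observation weights", {
  # molecules with per-molecule means m1 (n1 obs) and m2 (n2 obs)
  native <- make_obs(c("m1", "m2"), c(0L, 0L), c(7L, 7L),
                     list(c(1.0, 1.4), c(0.2, 0.4, 0.6)))
  ctrl <- build_control(make_obs("w", 0L, 7L, list(c(0.1, 0.3)),
                                 sample_type = "WGA"))
  sites <- make_sites(7L, 0L)
  ag <- agg_scores(native, ctrl, sites)
  m1 <- 1.2; n1 <- 2; m2 <- 0.4; n2 <- 3
  expect_equal(ag$score, (n1 * m1 + n2 * m2) / (n1 + n2) - 0.2,
               tolerance = 1e-12)
  expect_equal(ag$native_n, 5L)
  expect_equal(ag$wga_n, 2L)
  # single molecule: Agg_SN equals that molecule's SM_SN
  solo <- make_obs("only", 0L, 7L, list(c(0.9, 1.1)))
  expect_equal(agg_scores(solo, ctrl, sites)$score,
               smsn_scores(solo, ctrl, sites, min_cov = 1L)$score)
})

test_that("Agg_SN equals the cov-weighted mean of SM_SN scores", {
  set.seed(33)
  mols <- sprintf("m%d", 1:6)
  native <- make_obs(rep(mols, each = 1L), rep(0L, 6L), rep(4L, 6L),
                     lapply(1:6, function(i) rnorm(sample(1:5, 1L))))
  ctrl <- build_control(make_obs("w", 0L, 4L, list(rnorm(10)),
                                 sample_type = "WGA"))
  sites <- make_sites(4L, 0L)
  sm <- smsn_scores(native, ctrl, sites, min_cov = 1L)
  ag <- agg_scores(native, ctrl, sites)
  expect_equal(ag$score, weighted.mean(sm$score, sm$cov_sm),
               tolerance = 1e-9)
})

test_that("approximate SM_SN equals SM_SN against an all-zero control", {
  set.seed(40)
  native <- make_obs(c("a", "b"), c(0L, 1L), c(3L, 8L),
                     list(rnorm(4), rnorm(5)))
  zero_ctrl <- build_control(make_obs(c("w", "w"), c(0L, 1L), c(3L, 8L),
                                      list(0, 0), sample_type = "WGA"))
  sites <- make_sites(c(3L, 8L), c(0L, 1L))
  ap <- approx_smsn_scores(native, sites, min_cov = 1L)
  ref <- smsn_scores(native, zero_ctrl, sites, min_cov = 1L)
  expect_equal(ap$score, ref$score, tolerance = 1e-12)
  expect_true(attr(ap, "approximate"))
  expect_equal(nrow(approx_smsn_scores(native, make_sites(integer(), integer()),
                                       min_cov = 1L)), 0L)
})

test_that("SM_P pools covered sites and averages control means unweighted", {
  # molecule covering 2 sites, native pooled mean 1.9, control means 0.1/-0.1
  native <- make_obs(c("m", "m"), c(0L, 0L), c(2L, 9L),
                     list(c(1.8, 2.0), 1.9))
  ctrl <- build_control(make_obs(c("w", "w"), c(0L, 0L), c(2L, 9L),
                                 list(c(0.1, 0.1), -0.1),
                                 sample_type = "WGA"))
  sites <- make_sites(c(2L, 9L), c(0L, 0L))
  sp <- smp_scores(native, ctrl, sites, min_sites = 2L)
  expect_equal(sp$score, 1.9, tolerance = 1e-12)
  expect_equal(sp$n_sites, 2L)
  # below the site threshold: no score
  expect_equal(nrow(smp_scores(native, ctrl, sites, min_sites = 3L)), 0L)
  # a site without control drops out of both sides
  ctrl1 <- build_control(make_obs("w", 0L, 2L, list(c(0.1, 0.1)),
                                  sample_type = "WGA"))
  sp1 <- smp_scores(native, ctrl1, sites, min_sites = 1L)
  expect_equal(sp1$n_sites, 1L)
  expect_equal(sp1$score, 1.9 - 0.1, tolerance = 1e-12)
})

test_that("SM_P with one covered site reduces to pooled-position SM_SN", {
  native <- make_obs("m", 1L, 4L, list(c(0.5, 0.7, 0.9)))
  ctrl <- build_control(make_obs("w", 1L, 4L, list(c(0.2, 0.4)),
                                 sample_type = "WGA"))
  sites <- make_sites(4L, 1L)
  sp <- smp_scores(native, ctrl, sites, min_sites = 1L)
  sm <- smsn_scores(native, ctrl, sites, min_cov = 1L)
  expect_equal(sp$score, sm$score, tolerance = 1e-12)
})

test_that("IPD-unit mismatches between native and control are refused", {
  native <- make_obs("m", 0L, 1L, list(0.5))
  wga <- make_obs("w", 0L, 1L, list(0.1), sample_type = "WGA")
  setattr(wga, "ipd_unit", "frames")
  ctrl <- build_control(wga)
  expect_error(smsn_scores(native, ctrl, make_sites(1L, 0L), 1L),
               "unit mismatch")
})
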