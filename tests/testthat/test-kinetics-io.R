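test_that("TSV reader groups rows into subreads and handles empty input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ds0 <- make_dataset(make_subread("mol1", 0L, 0L, c("M", "M", "M"),
                                   ipd = c(0.5, 1.25, 2)))
  write_kinetics_tsv(ds0, path)
  ds <- read_kinetics_tsv(path, reference_length = 1000L)
  expect_equal(nrow(ds$events), 3L)
  expect_equal(nrow(unique(ds$events[, .(molecule_id, subread_index)])), 1L)
  expect_equal(ds$events$ipd, c(0.5, 1.25, 2))
  # header-only file -> zero subreads
  writeLines(readLines(path)[1L], path)
  expect_equal(nrow(read_kinetics_tsv(path)$events), 0L)
})

test_that("TSV round trip is byte-identical and preserves IPDs exactly", {
  sim <- simulate_dataset(quick_sim(101, n_molecules = 10L))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_kinetics_tsv(sim$dataset, p1)
  back <- read_kinetics_tsv(p1, reference_length = sim$dataset$reference_length)
  write_kinetics_tsv(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(back$events$ipd, sim$dataset$events$ipd, tolerance = 1e-8)
})

test_that("malformed rows are rejected with a line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ds <- make_dataset(make_subread("m", 0L, 0L, c("M", "M")))
  write_kinetics_tsv(ds, path)
  lines <- readLines(path)
  writeLines(c(lines, sub("\tM\t", "\tZ\t", lines[2L])), path)
  expect_error(read_kinetics_tsv(path), "unknown op.*line 4")
  bad <- lines
  bad[3L] <- sub("\t1$", "\tnotanumber", bad[3L])
  writeLines(bad, path)
  expect_error(read_kinetics_tsv(path), "non-numeric ipd.*line 3")
  bad <- lines
  bad[2L] <- sub("\t0\t254", "\t+\t254", bad[2L])
  writeLines(bad, path)
  expect_error(read_kinetics_tsv(path), "strand token")
})

test_that("score tables round-trip through TSV at 1e-9", {
  scores <- data.table(molecule_id = c("a", "b"), strand = c(0L, 1L),
                       ref_pos = c(10L, 20L), cov_sm = c(3L, 12L),
                       score = c(0.123456789123, -2.000000001))
  setattr(scores, "score_kind", "smsn")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scores(scores, path)
  back <- read_scores(path)
  expect_equal(attr(back, "score_kind"), "smsn")
  expect_equal(back$score, scores$score, tolerance = 1e-9)
  expect_equal(back$cov_sm, scores$cov_sm)
  # empty list -> header-only file
  empty <- scores[0L]
  setattr(empty, "score_kind", "smsn")
  write_scores(empty, path)
  expect_length(readLines(path), 1L)
})

test_that("mixed score kinds are refused", {
  smsn <- data.table(molecule_id = "a", strand = 0L, ref_pos = 1L,
                     cov_sm = 3L, score = 1)
  setattr(smsn, "score_kind", "smsn")
  smp <- data.table(molecule_id = "a", strand = 0L, n_sites = 12L, score = 1)
  setattr(smp, "score_kind", "smp")
  expect_error(write_scores(list(smsn, smp), tempfile()), "mixed score kinds")
})

test_that("SAM twin round-trips to the same dataset as its TSV twin", {
  dir <- withr::local_tempdir()
  cfg <- quick_sim(202, n_molecules = 6L)
  paths <- write_fixture_pair(cfg, dir, sam = TRUE, wga_n_molecules = 4L)
  tsv <- read_kinetics_tsv(paths$native, reference_length = cfg$reference_length)
  bam <- read_pacbio_bam(paths$native_sam, paths$reference,
                         ipd_unit = "seconds")
  a <- copy(tsv$events); b <- copy(bam$events)
  setorder(a, molecule_id, subread_index)
  setorder(b, molecule_id, subread_index)
  expect_equal(a$op, b$op)
  expect_equal(a$ref_pos, b$ref_pos)
  expect_equal(a$read_base, b$read_base)
  expect_equal(a$ref_base, b$ref_base)
  expect_equal(a$ipd, b$ipd, tolerance = 1e-6)
  expect_equal(a$mapqv, b$mapqv)
  expect_equal(a$accuracy, b$accuracy, tolerance = 1e-9)
})

test_that("BAM reader drops soft clips and skips unmapped reads", {
  sam <- withr::local_tempfile(fileext = ".sam")
  fa <- withr::local_tempfile(fileext = ".fa")
  refseq <- paste(rep("ACGT", 10L), collapse = "")
  writeLines(c(">chr1", refseq), fa)
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:40",
    paste("molA/0", 0, "chr1", 6, 254, "5S10M", "*", 0, 0,
          paste0("TTTTT", substr(refseq, 6, 15)), "*",
          paste0("ip:B:f,", paste(rep("1.5", 15), collapse = ",")),
          sep = "\t"),
    paste("molB/0", 4, "*", 0, 0, "*", "*", 0, 0, "ACGTACGTAC", "*",
          paste0("ip:B:f,", paste(rep("1", 10), collapse = ",")),
          sep = "\t")), sam)
  expect_warning(ds <- read_pacbio_bam(sam, fa), "unmapped")
  ev <- ds$events
  expect_equal(nrow(ev), 10L)                      # clipped bases dropped
  expect_true(all(ev$op == "M"))
  expect_equal(ev$ref_pos, 5:14)
  expect_equal(unique(ev$molecule_id), "molA")
  # a read without the ip tag is a hard error
  lines <- readLines(sam)
  writeLines(c(lines[1:2], sub("\tip:B:f.*$", "", lines[3L])), sam)
  expect_error(read_pacbio_bam(sam, fa), "ip")
})

test_that("BAM reference name mismatch is a hard error", {
  sam <- withr::local_tempfile(fileext = ".sam")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">other", "ACGTACGTACGTACGTACGT"), fa)
  writeLines(c(
    "@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:20",
    paste("m/0", 0, "chr1", 1, 254, "4M", "*", 0, 0, "ACGT", "*",
          "ip:B:f,1,1,1,1", sep = "\t")), sam)
  expect_error(read_pacbio_bam(sam, fa), "reference name mismatch")
})
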