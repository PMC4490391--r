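# Hand-built fixtures used across test files. Everything is constructed in
# code; no binary fixtures on disk.

suppressPackageStartupMessages(library(data.table))

# One subread as an event table. ops is a character vector like
# c("M","M","X","M"); ref positions are assigned along the given strand.
make_subread <- function(molecule_id, subread_index = 0L, strand = 0L,
                         ops, start = 0L, ipd = NULL, mapqv = 254L,
                         accuracy = NULL, ref_base = "A", read_base = NULL) {
  n <- length(ops)
  consumes <- ops %in% c("M", "X", "D")
  emits <- ops %in% c("M", "X", "I")
  ref_pos <- rep(NA_integer_, n)
  steps <- cumsum(consumes) - 1L
  if (strand == 0L) ref_pos[consumes] <- start + steps[consumes]
  else ref_pos[consumes] <- start - steps[consumes]
  if (is.null(ipd)) ipd <- rep(1, n)
  ipd[!emits] <- NA_real_
  rb <- rep(ref_base, n)
  rb[!consumes] <- NA_character_
  qb <- if (is.null(read_base)) rep(ref_base, n) else rep(read_base, n)
  qb[ops == "X"] <- setdiff(c("A", "C", "G", "T"), ref_base)[1L]
  qb[ops == "I"] <- "G"
  qb[!emits] <- NA_character_
  if (is.null(accuracy)) accuracy <- sum(ops == "M") / max(1L, sum(emits))
  data.table(molecule_id = molecule_id, subread_index = subread_index,
             strand = strand, mapqv = mapqv, accuracy = accuracy,
             ref_pos = ref_pos, op = ops, read_base = qb, ref_base = rb,
             ipd = ipd)
}

make_dataset <- function(..., reference_length = 1000L,
                         sample_type = "native", ipd_unit = "seconds") {
  kinetics_dataset(rbindlist(list(...)), reference_id = "ref",
                   reference_length = reference_length,
                   sample_type = sample_type, ipd_unit = ipd_unit)
}

# Clean-observation table built directly (bypassing preprocessing), for
# scoring oracles. values is a list: one numeric vector per row spec.
make_obs <- function(molecule_id, strand, ref_pos, values,
                     sample_type = "native") {
  rows <- rbindlist(lapply(seq_along(values), function(i)
    data.table(molecule_id = molecule_id[i], subread_index = 0L,
               strand = strand[i], ref_pos = ref_pos[i],
               log_ipd = values[[i]])))
  setattr(rows, "sample_type", sample_type)
  setattr(rows, "ipd_unit", "seconds")
  rows
}

make_sites <- function(ref_pos, strand, motif_name = "m") {
  data.table(ref_pos = as.integer(ref_pos), strand = as.integer(strand),
             motif_name = motif_name)
}

# small simulation config used by several files
quick_sim <- function(seed, n_molecules = 40L, ...) {
  sim_config(seed = seed, reference_length = 5000L, n_molecules = n_molecules,
             insert_mean = 200, insert_sd = 20, read_length = 4000L, ...)
}
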