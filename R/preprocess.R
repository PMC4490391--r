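# Subread filtering, error-adjacent masking, edge trimming and per-molecule
# log-IPD normalization. The product is one "clean observation" per surviving
# match event: a mean-centred natural-log IPD keyed by molecule, strand and
# reference position.

#' Preprocessing configuration
#'
#' Defaults follow the standard kinetic preprocessing for SMRT subreads:
#' subreads with ambiguous alignments (MapQV < 240), low accuracy (< 80%) or
#' short aligned length (< 100 bases) are removed; IPDs within one position
#' of any alignment error are masked; the first ten and last fifteen bases of
#' each subread are trimmed (adapter-transition bias); all surviving IPDs of
#' a molecule are natural-log-transformed and centred on the molecule's mean
#' (correcting slow drift of polymerase kinetics over a read).
#'
#' @param min_mapqv minimum mapping quality (subreads strictly below are
#'   removed).
#' @param min_accuracy minimum aligned identity, 0-1.
#' @param min_aligned_len minimum aligned length in bases (match + mismatch +
#'   deletion events).
#' @param error_mask_radius IPDs within this many read positions of a
#'   mismatch/insertion/deletion are masked (the error's own IPD always is).
#' @param head_trim,tail_trim events dropped from each subread's start / end.
#' @param zero_ipd_policy `"drop"` discards zero (or negative) IPDs, whose
#'   log is undefined; `"floor"` replaces them with `zero_ipd_floor`.
#' @param zero_ipd_floor floor value when `zero_ipd_policy = "floor"`.
#' @param mean_before_trim if `TRUE`, the per-molecule centring mean is
#'   computed before edge trimming (the default computes it on the final
#'   retained set, which makes the per-molecule zero-mean invariant exact).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(min_mapqv = 240L, min_accuracy = 0.80,
                              min_aligned_len = 100L, error_mask_radius = 1L,
                              head_trim = 10L, tail_trim = 15L,
                              zero_ipd_policy = c("drop", "floor"),
                              zero_ipd_floor = 1e-3,
                              mean_before_trim = FALSE) {
  zero_ipd_policy <- match.arg(zero_ipd_policy)
  cfg <- list(min_mapqv = as.integer(min_mapqv),
              min_accuracy = min_accuracy,
              min_aligned_len = as.integer(min_aligned_len),
              error_mask_radius = as.integer(error_mask_radius),
              head_trim = as.integer(head_trim),
              tail_trim = as.integer(tail_trim),
              zero_ipd_policy = zero_ipd_policy,
              zero_ipd_floor = zero_ipd_floor,
              mean_before_trim = isTRUE(mean_before_trim))
  stopifnot(cfg$min_mapqv >= 0, cfg$min_accuracy >= 0,
            cfg$min_aligned_len >= 0, cfg$error_mask_radius >= 0,
            cfg$head_trim >= 0, cfg$tail_trim >= 0, cfg$zero_ipd_floor > 0)
  structure(cfg, class = "preprocess_config")
}

#' @export
print.preprocess_config <- function(x, ...) {
  cat("<preprocess_config>\n")
  cat(sprintf("  filters: MapQV >= %d, accuracy >= %g, aligned length >= %d\n",
              x$min_mapqv, x$min_accuracy, x$min_aligned_len))
  cat(sprintf("  error mask radius %d; trim head %d / tail %d; zero-IPD: %s\n",
              x$error_mask_radius, x$head_trim, x$tail_trim,
              x$zero_ipd_policy))
  invisible(x)
}

#' Remove low-quality subreads
#'
#' Retains subreads with `mapqv >= min_mapqv`, `accuracy >= min_accuracy` and
#' aligned length (match/mismatch/deletion events) `>= min_aligned_len`;
#' thresholds are inclusive, mirroring the strict-inequality removal rules.
#'
#' @param ds a [kinetics_dataset()].
#' @param cfg a [preprocess_config()].
#' @return The filtered dataset (possibly with zero subreads).
#' @export
filter_subreads <- function(ds, cfg = preprocess_config()) {
  stopifnot(inherits(ds, "kinetics_dataset"))
  ev <- ds$events
  if (!nrow(ev)) return(ds)
  keep <- ev[, .(ok = mapqv[1L] >= cfg$min_mapqv &
                   accuracy[1L] >= cfg$min_accuracy &
                   sum(op != "I") >= cfg$min_aligned_len),
             by = .(molecule_id, subread_index)][ok == TRUE]
  replace_events(ds, ev[keep[, .(molecule_id, subread_index)],
                        on = c("molecule_id", "subread_index")])
}

#' Mask IPDs adjacent to alignment errors
#'
#' Sets to `NA` the IPD of every event whose read-order index lies within
#' `radius` positions of any mismatch, insertion or deletion in the same
#' subread; the error event's own IPD is always masked. Events are kept (so
#' edge trimming still sees the full subread); only their IPDs are removed
#' from consideration.
#'
#' @param ds a [kinetics_dataset()] (or a single-subread event table).
#' @param radius non-negative integer window half-width.
#' @return The dataset with masked IPDs.
#' @export
mask_error_adjacent <- function(ds, radius = 1L) {
  stopifnot(inherits(ds, "kinetics_dataset"), radius >= 0)
  ev <- copy(ds$events)
  if (!nrow(ev)) return(ds)
  radius <- as.integer(radius)
  mask_one <- function(err, r) {
    n <- length(err)
    cs <- cumsum(err)
    i <- seq_len(n)
    hi <- pmin(i + r, n)
    lo <- pmax(i - r, 1L)
    (cs[hi] - c(0L, cs)[lo]) > 0L
  }
  ev[, masked := mask_one(op != "M", radius),
     by = .(molecule_id, subread_index)]
  ev[masked == TRUE, ipd := NA_real_]
  ev[, masked := NULL]
  replace_events(ds, ev)
}

#' Trim subread edges
#'
#' Drops the first `head` and last `tail` events (in read order) of every
#' subread; a subread with `<= head + tail` events yields nothing.
#'
#' @param ds a [kinetics_dataset()].
#' @param head,tail non-negative trim counts.
#' @return The trimmed dataset.
#' @export
trim_edges <- function(ds, head = 10L, tail = 15L) {
  stopifnot(inherits(ds, "kinetics_dataset"), head >= 0, tail >= 0)
  ev <- ds$events
  if (!nrow(ev) || (head == 0L && tail == 0L)) return(ds)
  ev <- copy(ev)
  ev[, `:=`(.idx = seq_len(.N), .n = .N), by = .(molecule_id, subread_index)]
  ev <- ev[.idx > head & .idx <= .n - tail]
  ev[, c(".idx", ".n") := NULL]
  replace_events(ds, ev)
}

#' Log-transform and centre surviving IPDs per molecule
#'
#' Takes the natural log of every surviving match-event IPD and subtracts,
#' per molecule, the mean over all of that molecule's subreads. Mismatch,
#' insertion and deletion events never contribute observations. Zero IPDs
#' are handled per the config's `zero_ipd_policy`.
#'
#' @param ds a filtered/masked/trimmed [kinetics_dataset()].
#' @param cfg a [preprocess_config()].
#' @return A data.table of clean observations with columns `molecule_id`,
#'   `subread_index`, `strand`, `ref_pos`, `log_ipd`, carrying the dataset's
#'   `sample_type`, `ipd_unit`, `reference_id` and `reference_length` as
#'   attributes plus `n_zero_dropped`.
#' @export
normalize_and_log <- function(ds, cfg = preprocess_config()) {
  stopifnot(inherits(ds, "kinetics_dataset"))
  obs <- ds$events[op == "M" & !is.na(ipd),
                   .(molecule_id, subread_index, strand, ref_pos, ipd)]
  n_zero <- obs[ipd <= 0, .N]
  if (cfg$zero_ipd_policy == "drop") {
    obs <- obs[ipd > 0]
    if (n_zero > 0L)
      message("dropped ", n_zero, " non-positive IPD value(s)")
  } else {
    obs[ipd <= 0, ipd := cfg$zero_ipd_floor]
  }
  obs[, log_ipd := log(ipd)]
  obs[, log_ipd := log_ipd - mean(log_ipd), by = molecule_id]
  obs[, ipd := NULL]
  as_observations(obs, ds, n_zero_dropped = n_zero)
}

as_observations <- function(obs, ds, n_zero_dropped = 0L) {
  setattr(obs, "sample_type", ds$sample_type)
  setattr(obs, "ipd_unit", ds$ipd_unit)
  setattr(obs, "reference_id", ds$reference_id)
  setattr(obs, "reference_length", ds$reference_length)
  setattr(obs, "n_zero_dropped", n_zero_dropped)
  obs[]
}

#' Full preprocessing pipeline
#'
#' `filter_subreads()` then [mask_error_adjacent()] then [trim_edges()] then
#' [normalize_and_log()]. With `mean_before_trim = TRUE` the centring mean is
#' computed after masking but before trimming.
#'
#' @param ds a [kinetics_dataset()].
#' @param cfg a [preprocess_config()].
#' @return Clean observations as from [normalize_and_log()].
#' @export
preprocess <- function(ds, cfg = preprocess_config()) {
  ds <- filter_subreads(ds, cfg)
  ds <- mask_error_adjacent(ds, cfg$error_mask_radius)
  if (cfg$mean_before_trim) {
    pre <- ds$events[op == "M" & !is.na(ipd) & ipd > 0,
                     .(mol_mean = mean(log(ipd))), by = molecule_id]
    ds <- trim_edges(ds, cfg$head_trim, cfg$tail_trim)
    obs <- ds$events[op == "M" & !is.na(ipd),
                     .(molecule_id, subread_index, strand, ref_pos, ipd)]
    n_zero <- obs[ipd <= 0, .N]
    obs <- obs[ipd > 0]
    obs[pre, mol_mean := i.mol_mean, on = "molecule_id"]
    obs[, log_ipd := log(ipd) - mol_mean]
    obs[, c("ipd", "mol_mean") := NULL]
    return(as_observations(obs, ds, n_zero_dropped = n_zero))
  }
  ds <- trim_edges(ds, cfg$head_trim, cfg$tail_trim)
  normalize_and_log(ds, cfg)
}
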