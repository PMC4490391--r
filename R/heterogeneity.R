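# Negative-control construction, in-silico mixing, coverage downsampling and
# the sensitivity/specificity evaluation harness.

#' IPD-shuffled SM_P negative control
#'
#' Randomly permutes the normalized log-IPD values among all motif-site
#' observation slots (molecule, strand, site), preserving each molecule's
#' covered-site structure and per-slot observation counts, then recomputes
#' SM_P on the shuffled data. Because any non-methylated IPDs are dispersed
#' across molecules, the shuffled distribution reflects molecules carrying
#' the population-average methylation level and serves as the negative
#' control for calling non-methylated molecules.
#'
#' @inheritParams smp_scores
#' @param seed RNG seed for the permutation.
#' @return SM_P scores as from [smp_scores()], with attribute
#'   `shuffled = TRUE`.
#' @export
shuffle_control_smp <- function(native_obs, control, sites, min_sites = 10L,
                                seed = 1L) {
  obs <- copy(as.data.table(native_obs))
  sites_dt <- as.data.table(sites)[, .(strand, ref_pos)]
  obs[, .at_site := FALSE]
  obs[sites_dt, .at_site := TRUE, on = c("strand", "ref_pos")]
  idx <- which(obs$.at_site)
  if (length(idx) > 1L)
    with_seed(seed, obs[idx, log_ipd := log_ipd[sample.int(.N)]])
  obs[, .at_site := NULL]
  for (a in c("sample_type", "ipd_unit", "reference_id", "reference_length"))
    setattr(obs, a, attr(native_obs, a))
  out <- smp_scores(obs, control, sites, min_sites = min_sites)
  setattr(out, "shuffled", TRUE)
  out
}

#' In-silico mixture of native and WGA molecules
#'
#' Samples molecules without replacement — `round(native_fraction * n_total)`
#' from the native dataset, the remainder from the WGA dataset — relabels
#' them to avoid ID collisions, and returns the combined set typed as native
#' (it plays the native role downstream). Used to validate methylated-
#' fraction estimation against known mixing proportions.
#'
#' @param native_ds,wga_ds [kinetics_dataset()]s on the same reference with
#'   the same IPD unit.
#' @param native_fraction fraction of molecules drawn from the native set.
#' @param n_total total number of molecules in the mixture.
#' @param seed RNG seed.
#' @return A [kinetics_dataset()] with `sample_type = "native"`.
#' @export
insilico_mix <- function(native_ds, wga_ds, native_fraction, n_total,
                         seed = 1L) {
  stopifnot(inherits(native_ds, "kinetics_dataset"),
            inherits(wga_ds, "kinetics_dataset"),
            native_fraction >= 0, native_fraction <= 1, n_total >= 1)
  if (!identical(native_ds$ipd_unit, wga_ds$ipd_unit))
    stop("IPD unit mismatch between native and WGA datasets")
  if (!identical(native_ds$reference_id, wga_ds$reference_id))
    stop("datasets are aligned to different references")
  n_nat <- round(native_fraction * n_total)
  n_wga <- n_total - n_nat
  nat_ids <- unique(native_ds$events$molecule_id)
  wga_ids <- unique(wga_ds$events$molecule_id)
  if (length(nat_ids) < n_nat)
    stop("need ", n_nat, " native molecules but only ", length(nat_ids),
         " available (shortfall ", n_nat - length(nat_ids), ")")
  if (length(wga_ids) < n_wga)
    stop("need ", n_wga, " WGA molecules but only ", length(wga_ids),
         " available (shortfall ", n_wga - length(wga_ids), ")")
  picked <- with_seed(seed, list(
    nat = sample(nat_ids, n_nat),
    wga = sample(wga_ids, n_wga)))
  nat_ev <- native_ds$events[molecule_id %in% picked$nat]
  wga_ev <- wga_ds$events[molecule_id %in% picked$wga]
  nat_ev <- copy(nat_ev)[, molecule_id := paste0("nat:", molecule_id)]
  wga_ev <- copy(wga_ev)[, molecule_id := paste0("wga:", molecule_id)]
  kinetics_dataset(rbind(nat_ev, wga_ev), native_ds$reference_id,
                   max(native_ds$reference_length, wga_ds$reference_length),
                   sample_type = "native", ipd_unit = native_ds$ipd_unit,
                   provenance = list(mix = list(native_fraction = native_fraction,
                                                n_total = n_total, seed = seed)),
                   validate = FALSE)
}

#' Downsample molecules to a target genomic coverage
#'
#' Retains a uniformly random subset of molecules whose total aligned bases
#' divided by the reference length approximate the target coverage (to
#' within one molecule). Emulates reduced genomic sequencing coverage while
#' leaving per-molecule coverage (`cov_sm`) untouched. For a score table,
#' where aligned bases are no longer known, supply `current_coverage` and a
#' `round(target/current * n_molecules)` subset of molecules is kept.
#'
#' @param x a [kinetics_dataset()] or a score table.
#' @param target_coverage desired genomic coverage (aligned bases /
#'   reference length).
#' @param reference_length defaults to the dataset's own.
#' @param seed RNG seed.
#' @param current_coverage required for score tables.
#' @return Object of the same type as `x`, subset to the retained molecules.
#' @export
downsample_molecules <- function(x, target_coverage, reference_length = NULL,
                                 seed = 1L, current_coverage = NULL) {
  stopifnot(target_coverage >= 0)
  if (inherits(x, "kinetics_dataset")) {
    reference_length <- reference_length %||% x$reference_length
    bases <- x$events[, .(aligned = sum(op != "I")), by = molecule_id]
    total_cov <- sum(bases$aligned) / reference_length
    if (target_coverage >= total_cov) {
      if (target_coverage > total_cov)
        warning(sprintf(
          "target coverage %.3g exceeds available %.3g; returning all molecules",
          target_coverage, total_cov))
      return(x)
    }
    ord <- with_seed(seed, sample.int(nrow(bases)))
    cum <- cumsum(bases$aligned[ord]) / reference_length
    k <- findInterval(target_coverage, cum) + 1L
    k <- min(k, nrow(bases))
    subset_molecules(x, bases$molecule_id[ord[seq_len(k)]])
  } else {
    if (is.null(current_coverage))
      stop("current_coverage is required when downsampling a score table")
    dt <- as.data.table(x)
    ids <- unique(dt$molecule_id)
    frac <- min(1, target_coverage / current_coverage)
    k <- max(1L, round(frac * length(ids)))
    keep <- with_seed(seed, sample(ids, k))
    out <- dt[molecule_id %in% keep]
    for (a in c("score_kind", "approximate"))
      setattr(out, a, attr(x, a))
    out[]
  }
}

#' Sensitivity/specificity evaluation grid
#'
#' Treating the positive scores as truly methylated (e.g. native data for a
#' motif assumed fully methylated, or synthetic truth) and the negative
#' scores as unmethylated (WGA), tabulates, for each minimum-coverage bin
#' and score threshold: sensitivity = fraction of positives at or above the
#' threshold, specificity = fraction of negatives below it. The coverage
#' column is `cov_sm` for SM_SN scores and `n_sites` for SM_P scores.
#'
#' @param pos_scores,neg_scores score tables of the same kind.
#' @param min_cov_grid coverage thresholds to evaluate (scores with coverage
#'   `>=` the threshold enter the bin).
#' @param thresholds score thresholds to evaluate.
#' @return data.table with columns `min_cov`, `threshold`, `n_pos`, `n_neg`,
#'   `sensitivity`, `specificity`; empty bins are omitted with a warning.
#' @export
sensitivity_specificity <- function(pos_scores, neg_scores,
                                    min_cov_grid = c(2L, 10L, 15L),
                                    thresholds = seq(-1, 3, by = 0.1)) {
  covcol <- if ("cov_sm" %in% names(pos_scores)) "cov_sm" else "n_sites"
  pos <- as.data.table(pos_scores)
  neg <- as.data.table(neg_scores)
  rows <- list()
  for (mc in min_cov_grid) {
    p <- pos[get(covcol) >= mc, score]
    n <- neg[get(covcol) >= mc, score]
    if (!length(p) || !length(n)) {
      warning("empty bin at min coverage ", mc, "; omitted")
      next
    }
    rows[[length(rows) + 1L]] <- data.table(
      min_cov = mc, threshold = thresholds,
      n_pos = length(p), n_neg = length(n),
      sensitivity = vapply(thresholds, function(t) mean(p >= t), numeric(1)),
      specificity = vapply(thresholds, function(t) mean(n < t), numeric(1)))
  }
  rbindlist(rows)
}
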