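# The three methylation statistics:
#   SM_SN  - single-molecule, single-nucleotide: per-molecule mean log IPD at
#            a motif position minus the WGA position/strand-matched mean.
#   Agg_SN - molecule-aggregated analogue (population-level score).
#   SM_P   - single-molecule pooled: per-molecule mean log IPD pooled over
#            all covered motif sites on a strand, minus the mean of the WGA
#            per-site means over the same sites (epigenetic phasing score).
# Plus the WGA-free approximate SM_SN used when no amplified control exists.

obs_sample_type <- function(obs) attr(obs, "sample_type") %||% "native"

check_units <- function(native_obs, control) {
  nu <- attr(native_obs, "ipd_unit")
  cu <- attr(control, "ipd_unit")
  if (!is.null(nu) && !is.null(cu) && !identical(nu, cu))
    stop("IPD unit mismatch between native (", nu, ") and control (", cu,
         ") data; units are never converted implicitly")
}

#' Build the WGA kinetic control lookup
#'
#' Aggregates whole-genome-amplified (methylation-free) observations across
#' all molecules, storing the mean normalized log IPD and observation count
#' per (strand, reference position). This is the context-matched baseline
#' that the scoring statistics subtract.
#'
#' @param wga_obs clean observations from [preprocess()] of a dataset with
#'   `sample_type = "WGA"`.
#' @return A keyed data.table of class `control_lookup` with columns
#'   `strand`, `ref_pos`, `mean_log_ipd`, `n`.
#' @export
build_control <- function(wga_obs) {
  if (obs_sample_type(wga_obs) != "WGA")
    stop("control must be built from WGA observations, got sample_type '",
         obs_sample_type(wga_obs), "'")
  ctrl <- as.data.table(wga_obs)[, .(mean_log_ipd = mean(log_ipd), n = .N),
                                 by = .(strand, ref_pos)]
  setkey(ctrl, strand, ref_pos)
  setattr(ctrl, "ipd_unit", attr(wga_obs, "ipd_unit"))
  setattr(ctrl, "class", c("control_lookup", class(ctrl)))
  ctrl[]
}

#' @export
print.control_lookup <- function(x, ...) {
  cat(sprintf("<control_lookup> %d (strand, position) keys; mean depth %.1f\n",
              nrow(x), mean(x$n)))
  invisible(x)
}

site_obs <- function(native_obs, sites) {
  obs <- as.data.table(native_obs)
  obs[as.data.table(sites)[, .(strand, ref_pos)],
      on = c("strand", "ref_pos"), nomatch = NULL]
}

skip_report <- function(scores, ...) {
  setattr(scores, "skip_report", list(...))
  scores
}

#' Single-molecule, single-nucleotide (SM_SN) scores
#'
#' For each (molecule, strand, motif-site position) with at least `min_cov`
#' surviving IPD observations and a control entry, the score is the
#' molecule's mean normalized log IPD at that strand/position minus the WGA
#' strand/position-matched mean. Groups failing the coverage or control
#' condition are skipped and counted in the table's `skip_report` attribute.
#'
#' @param native_obs clean observations from [preprocess()] of native data.
#' @param control a [build_control()] lookup.
#' @param sites motif sites from [find_motif_sites()].
#' @param min_cov minimum single-molecule coverage `cov_sm` (default 10).
#' @return data.table with columns `molecule_id`, `strand`, `ref_pos`,
#'   `cov_sm`, `score` (attribute `score_kind = "smsn"`).
#' @export
smsn_scores <- function(native_obs, control, sites, min_cov = 10L) {
  stopifnot(min_cov >= 1L)
  check_units(native_obs, control)
  g <- site_obs(native_obs, sites)[
    , .(cov_sm = .N, mol_mean = mean(log_ipd)),
    by = .(molecule_id, strand, ref_pos)]
  g[control, ctrl_mean := i.mean_log_ipd, on = c("strand", "ref_pos")]
  n_low <- g[cov_sm < min_cov, .N]
  n_noctrl <- g[cov_sm >= min_cov & is.na(ctrl_mean), .N]
  out <- g[cov_sm >= min_cov & !is.na(ctrl_mean),
           .(molecule_id, strand, ref_pos, cov_sm,
             score = mol_mean - ctrl_mean)]
  setorder(out, molecule_id, strand, ref_pos)
  setattr(out, "score_kind", "smsn")
  skip_report(out, low_coverage = n_low, no_control = n_noctrl)
}

#' Molecule-aggregated single-nucleotide (Agg_SN) scores
#'
#' Population-level analogue of SM_SN: per (strand, motif-site position),
#' the mean over all native observations pooled across molecules minus the
#' WGA mean; emitted only where both native and control data exist.
#'
#' @inheritParams smsn_scores
#' @return data.table with columns `strand`, `ref_pos`, `native_n`, `wga_n`,
#'   `score` (attribute `score_kind = "agg"`).
#' @export
agg_scores <- function(native_obs, control, sites) {
  check_units(native_obs, control)
  g <- site_obs(native_obs, sites)[
    , .(native_n = .N, native_mean = mean(log_ipd)),
    by = .(strand, ref_pos)]
  g[control, `:=`(ctrl_mean = i.mean_log_ipd, wga_n = i.n),
    on = c("strand", "ref_pos")]
  out <- g[!is.na(ctrl_mean),
           .(strand, ref_pos, native_n, wga_n,
             score = native_mean - ctrl_mean)]
  setorder(out, ref_pos, strand)
  setattr(out, "score_kind", "agg")
  out[]
}

#' Approximate SM_SN scores without a WGA control
#'
#' When no amplified control exists, the score is simply the native
#' molecule/strand/position mean normalized log IPD. Susceptible to local
#' sequence-context IPD bias, but sufficient to resolve methylated and
#' non-methylated components of a bimodal distribution.
#'
#' @inheritParams smsn_scores
#' @return As [smsn_scores()], with attribute `approximate = TRUE`.
#' @export
approx_smsn_scores <- function(native_obs, sites, min_cov = 10L) {
  stopifnot(min_cov >= 1L)
  g <- site_obs(native_obs, sites)[
    , .(cov_sm = .N, score = mean(log_ipd)),
    by = .(molecule_id, strand, ref_pos)]
  n_low <- g[cov_sm < min_cov, .N]
  out <- g[cov_sm >= min_cov,
           .(molecule_id, strand, ref_pos, cov_sm, score)]
  setorder(out, molecule_id, strand, ref_pos)
  setattr(out, "score_kind", "smsn")
  setattr(out, "approximate", TRUE)
  skip_report(out, low_coverage = n_low, no_control = 0L)
}

#' Single-molecule pooled (SM_P) phasing scores
#'
#' Per (molecule, strand): the molecule's surviving normalized log IPDs at
#' all motif-site positions on that strand are pooled irrespective of
#' genomic position and averaged; subtracted from this is the unweighted
#' mean, over the same covered sites, of the WGA per-site mean log IPDs.
#' Sites lacking a control entry are excluded from both sides. Scores are
#' emitted only for molecule/strands covering at least `min_sites` sites.
#'
#' @inheritParams smsn_scores
#' @param min_sites minimum number of covered motif sites (default 10).
#' @return data.table with columns `molecule_id`, `strand`, `n_sites`,
#'   `score` (attribute `score_kind = "smp"`).
#' @export
smp_scores <- function(native_obs, control, sites, min_sites = 10L) {
  stopifnot(min_sites >= 1L)
  check_units(native_obs, control)
  so <- site_obs(native_obs, sites)
  so[control, ctrl_mean := i.mean_log_ipd, on = c("strand", "ref_pos")]
  n_noctrl <- if (nrow(so)) uniqueN(so[is.na(ctrl_mean),
                                       .(molecule_id, strand, ref_pos)]) else 0L
  so <- so[!is.na(ctrl_mean)]
  # per covered site: pooled native obs count and the site's control mean
  per_site <- so[, .(n_obs = .N, obs_sum = sum(log_ipd),
                     ctrl_mean = ctrl_mean[1L]),
                 by = .(molecule_id, strand, ref_pos)]
  g <- per_site[, .(n_sites = .N,
                    score = sum(obs_sum) / sum(n_obs) - mean(ctrl_mean)),
                by = .(molecule_id, strand)]
  n_few <- g[n_sites < min_sites, .N]
  out <- g[n_sites >= min_sites]
  setorder(out, molecule_id, strand)
  setattr(out, "score_kind", "smp")
  skip_report(out, too_few_sites = n_few, sites_without_control = n_noctrl)
}
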