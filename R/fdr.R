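# Empirical FDR for molecule-level methylation calls: the tail ratio of a
# matched negative-control SM_P distribution to the observed native SM_P
# distribution, monotone-adjusted and capped at 1. Methylated calls use a
# WGA control; non-methylated calls use an IPD-shuffled control.

#' Empirical FDR curve for molecule calls
#'
#' At each candidate threshold `t` (the sorted distinct native scores),
#' `FDR(t) = min(1, frac(control beyond t) / frac(native beyond t))`, where
#' "beyond" means `>= t` for `direction = "greater"` (methylated calls) and
#' `<= t` for `direction = "less"` (non-methylated calls). The curve is
#' adjusted to be non-increasing as the threshold becomes more extreme.
#'
#' @param native_scores native SM_P score table (or numeric vector).
#' @param control_scores negative-control score table (or numeric vector):
#'   WGA-derived for methylated calls, IPD-shuffled for non-methylated calls.
#' @param direction `"greater"` or `"less"`.
#' @param q FDR cap at which the callable fraction is reported (default 1%).
#' @return data.table of class `fdr_curve` with columns `threshold`,
#'   `native_beyond`, `control_beyond`, `native_frac`, `control_frac`,
#'   `fdr` (monotone-adjusted); attributes `direction`, `q` and
#'   `call_fraction` (fraction of native molecules beyond the least extreme
#'   threshold with adjusted FDR <= q; 0 when none qualifies).
#' @export
empirical_fdr <- function(native_scores, control_scores,
                          direction = c("greater", "less"), q = 0.01) {
  direction <- match.arg(direction)
  nat <- if (is.data.frame(native_scores)) native_scores$score else
    as.numeric(native_scores)
  ctl <- if (is.data.frame(control_scores)) control_scores$score else
    as.numeric(control_scores)
  if (!length(nat) || !length(ctl))
    stop("both native and control score sets must be non-empty")
  sgn <- if (direction == "greater") 1 else -1
  x <- sgn * nat
  y <- sgn * ctl
  thr <- sort(unique(x))                       # increasingly extreme
  n_nat <- length(x); n_ctl <- length(y)
  nat_beyond <- n_nat - findInterval(thr, sort(x), left.open = TRUE)
  ctl_beyond <- n_ctl - findInterval(thr, sort(y), left.open = TRUE)
  if (all(nat_beyond == 0L)) {
    warning("no native scores beyond any threshold; empty FDR curve")
    out <- data.table(threshold = numeric(), native_beyond = integer(),
                      control_beyond = integer(), native_frac = numeric(),
                      control_frac = numeric(), fdr = numeric())
  } else {
    nat_frac <- nat_beyond / n_nat
    ctl_frac <- ctl_beyond / n_ctl
    fdr_raw <- pmin(1, ctl_frac / nat_frac)
    # running minimum from the least extreme threshold: non-increasing in
    # extremity without letting chance zeros in the sparse far tail (one
    # native score beyond the last control) collapse the whole curve
    fdr <- cummin(fdr_raw)
    out <- data.table(threshold = sgn * thr, native_beyond = nat_beyond,
                      control_beyond = ctl_beyond, native_frac = nat_frac,
                      control_frac = ctl_frac, fdr = fdr)
  }
  ok <- which(out$fdr <= q)
  call_fraction <- if (length(ok)) out$native_frac[min(ok)] else 0
  setattr(out, "direction", direction)
  setattr(out, "q", q)
  setattr(out, "call_fraction", call_fraction)
  setattr(out, "class", c("fdr_curve", class(out)))
  out[]
}

#' Fraction of native molecules callable at an FDR cap
#' @param curve an [empirical_fdr()] curve.
#' @param q FDR cap; defaults to the cap stored on the curve.
#' @return Fraction of native scores beyond the least extreme threshold
#'   whose adjusted FDR is `<= q`.
#' @export
fdr_call_fraction <- function(curve, q = attr(curve, "q")) {
  stopifnot(inherits(curve, "fdr_curve"))
  ok <- which(curve$fdr <= q)
  if (length(ok)) curve$native_frac[min(ok)] else 0
}

#' @export
print.fdr_curve <- function(x, ...) {
  cat(sprintf("<fdr_curve> direction '%s', %d thresholds\n",
              attr(x, "direction"), nrow(x)))
  cat(sprintf("  callable native fraction at FDR <= %g: %.4g\n",
              attr(x, "q"), attr(x, "call_fraction")))
  invisible(x)
}
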