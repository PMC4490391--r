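# Two-component Gaussian mixture fit by expectation-maximisation, used to
# estimate the methylated fraction of a motif from a distribution of
# single-molecule scores. The methylated and non-methylated populations of a
# 6mA motif centre near score 2 and score 0 respectively, so the weight of
# the higher-mean component is the methylated-fraction readout.

dnorm_safe <- function(x, mean, sd) pmax(stats::dnorm(x, mean, sd), 1e-300)

mix_loglik <- function(x, w, mu, sd) {
  sum(log(w[1L] * dnorm_safe(x, mu[1L], sd[1L]) +
          w[2L] * dnorm_safe(x, mu[2L], sd[2L])))
}

run_em <- function(x, w, mu, sd, tol, max_iter, sd_floor) {
  n <- length(x)
  ll <- mix_loglik(x, w, mu, sd)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E step
    d1 <- w[1L] * dnorm_safe(x, mu[1L], sd[1L])
    d2 <- w[2L] * dnorm_safe(x, mu[2L], sd[2L])
    g2 <- d2 / (d1 + d2)
    g1 <- 1 - g2
    # M step
    n1 <- sum(g1); n2 <- sum(g2)
    if (n1 < 1e-8 || n2 < 1e-8) break  # component emptied
    w <- c(n1, n2) / n
    mu <- c(sum(g1 * x) / n1, sum(g2 * x) / n2)
    sd <- pmax(sqrt(c(sum(g1 * (x - mu[1L])^2) / n1,
                      sum(g2 * (x - mu[2L])^2) / n2)), sd_floor)
    ll_new <- mix_loglik(x, w, mu, sd)
    if (abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  list(w = w, mu = mu, sd = sd, loglik = ll, n_iter = iter,
       converged = converged)
}

#' Fit a two-component Gaussian mixture to scores by EM
#'
#' Self-contained expectation-maximisation for a 1-D two-Gaussian mixture,
#' with deterministic initialisation (a median split plus a k-means split;
#' optionally one extra seeded random restart) and a standard-deviation
#' floor preventing component collapse. A one-component Gaussian is fitted
#' alongside and the two models are compared by BIC, so that a sample drawn
#' from a single population (e.g. a fully methylated or fully non-methylated
#' motif) is reported as one effective component instead of an arbitrary
#' split; because BIC is conservative for moderately separated components at
#' small n, a fitted pair separated by at least two pooled standard
#' deviations whose minor component carries at least 10 expected
#' observations is kept as two components regardless. Components are
#' reported ordered by mean.
#'
#' @param scores numeric vector of at least 20 scores (an SM_SN or SM_P
#'   score table is also accepted; its `score` column is used).
#' @param tol EM stops when the log-likelihood gain drops below `tol`.
#' @param max_iter maximum EM iterations per start.
#' @param sd_floor lower bound on component standard deviations.
#' @param seed optional; adds one random restart drawn under this seed.
#' @return An object of class `smalr_mixfit` with elements `weights`,
#'   `means`, `sds` (low/high component), `loglik`, `n_iter`, `converged`,
#'   `n`, `n_components` (BIC choice), `bic` and the one-component fit.
#' @export
fit_two_gaussian_em <- function(scores, tol = 1e-6, max_iter = 1000L,
                                sd_floor = 1e-3, seed = NULL) {
  x <- if (is.data.frame(scores)) as.numeric(scores$score) else
    as.numeric(scores)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20L)
    stop("need at least 20 finite scores to fit a mixture, got ", n)
  cl <- match.call()
  single <- list(mean = mean(x), sd = max(sqrt(mean((x - mean(x))^2)),
                                          sd_floor))
  ll1 <- sum(stats::dnorm(x, single$mean, single$sd, log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  if (diff(range(x)) < .Machine$double.eps^0.5) {
    # degenerate input: all values identical
    warning("all scores identical; single-component fallback")
    fit <- new_mixfit(weights = if (single$mean > 0) c(0, 1) else c(1, 0),
                      means = rep(single$mean, 2L), sds = rep(single$sd, 2L),
                      loglik = ll1, n_iter = 0L, converged = TRUE, n = n,
                      n_components = 1L, bic = c(`1` = bic1, `2` = NA_real_),
                      single = single, call = cl, data = x)
    return(fit)
  }
  starts <- list(median_split_init(x, sd_floor),
                 kmeans_init(x, sd_floor))
  if (!is.null(seed))
    starts <- c(starts, list(random_init(x, sd_floor, seed)))
  runs <- lapply(starts, function(s)
    run_em(x, s$w, s$mu, s$sd, tol, max_iter, sd_floor))
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
  ord <- order(best$mu)
  bic2 <- -2 * best$loglik + 5 * log(n)
  # one population or two? BIC compares global fit but is conservative for
  # moderately separated components at small n, so a clearly resolved pair
  # (>= 2 pooled-sd separation, minor component carrying >= 10 expected
  # observations) is kept as two components even when BIC prefers one.
  separation <- abs(diff(best$mu)) / max(best$sd)
  minor_n <- min(best$w) * n
  two <- bic2 < bic1 || (separation >= 2 && minor_n >= 10)
  new_mixfit(weights = best$w[ord], means = best$mu[ord], sds = best$sd[ord],
             loglik = best$loglik, n_iter = best$n_iter,
             converged = best$converged, n = n,
             n_components = if (two) 2L else 1L,
             bic = c(`1` = bic1, `2` = bic2), single = single, call = cl,
             data = x)
}

median_split_init <- function(x, sd_floor) {
  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  if (!length(hi)) { lo <- x[x < med]; hi <- x[x >= med] }
  list(w = c(length(lo), length(hi)) / length(x),
       mu = c(mean(lo), mean(hi)),
       sd = pmax(c(stats::sd(lo), stats::sd(hi)), sd_floor, na.rm = TRUE))
}

kmeans_init <- function(x, sd_floor) {
  centers <- unique(stats::quantile(x, c(0.25, 0.75), names = FALSE))
  if (length(centers) < 2L) return(median_split_init(x, sd_floor))
  km <- suppressWarnings(stats::kmeans(x, centers = matrix(centers)))
  grp <- km$cluster
  mu <- tapply(x, grp, mean)
  sd <- tapply(x, grp, stats::sd)
  sd[is.na(sd)] <- sd_floor
  list(w = as.numeric(table(grp)) / length(x),
       mu = as.numeric(mu), sd = pmax(as.numeric(sd), sd_floor))
}

random_init <- function(x, sd_floor, seed) {
  with_seed(seed, {
    mu <- sample(x, 2L)
    list(w = c(0.5, 0.5), mu = sort(mu),
         sd = rep(max(stats::sd(x) / 2, sd_floor), 2L))
  })
}

new_mixfit <- function(weights, means, sds, loglik, n_iter, converged, n,
                       n_components, bic, single, call, data = NULL) {
  structure(list(weights = weights, means = means, sds = sds,
                 loglik = loglik, n_iter = n_iter, converged = converged,
                 n = n, n_components = n_components, bic = bic,
                 single = single, call = call, data = data),
            class = "smalr_mixfit")
}

#' Methylated fraction from a mixture fit
#'
#' Reads out the weight of the higher-mean component (the methylated
#' population on the score scale, where methylated 6mA sites centre near 2
#' and non-methylated sites near 0). If model selection kept a single
#' component, the whole sample is one population: the fraction is 1 when
#' its mean lies above `midpoint` (half the canonical 6mA score shift) and
#' 0 otherwise.
#'
#' @param fit a `smalr_mixfit` from [fit_two_gaussian_em()].
#' @param midpoint score value separating the non-methylated and methylated
#'   locations, used only for the single-component readout.
#' @return Fraction in `[0, 1]`.
#' @export
methylated_fraction <- function(fit, midpoint = 1) {
  stopifnot(inherits(fit, "smalr_mixfit"))
  if (fit$n_components == 1L) {
    # one population; assign it by which side of the class midpoint it sits
    return(if (fit$single$mean > midpoint) 1 else 0)
  }
  if (!fit$converged) {
    cond <- simpleError("mixture fit did not converge")
    cond$fit <- fit
    stop(cond)
  }
  if (abs(diff(fit$means)) < .Machine$double.eps^0.5)
    stop("mixture components have equal means; no separable ",
         "methylated/non-methylated populations")
  fit$weights[2L]
}

#' @export
print.smalr_mixfit <- function(x, ...) {
  cat("<smalr_mixfit> two-component Gaussian mixture, n =", x$n, "\n")
  cat(sprintf("  low : weight %.4f, mean %8.4f, sd %.4f\n",
              x$weights[1L], x$means[1L], x$sds[1L]))
  cat(sprintf("  high: weight %.4f, mean %8.4f, sd %.4f\n",
              x$weights[2L], x$means[2L], x$sds[2L]))
  cat(sprintf("  loglik %.2f after %d iterations (%s); BIC prefers %d component(s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "not converged",
              x$n_components))
  invisible(x)
}

#' @export
summary.smalr_mixfit <- function(object, ...) {
  print(object)
  frac <- tryCatch(methylated_fraction(object), error = function(e) NA_real_)
  if (!is.na(frac))
    cat(sprintf("  methylated fraction (high-component weight): %.4f\n", frac))
  invisible(object)
}

#' @export
coef.smalr_mixfit <- function(object, ...) {
  c(weight_lo = object$weights[1L], weight_hi = object$weights[2L],
    mean_lo = object$means[1L], mean_hi = object$means[2L],
    sd_lo = object$sds[1L], sd_hi = object$sds[2L])
}

#' @export
logLik.smalr_mixfit <- function(object, ...) {
  structure(object$loglik,
            df = if (object$n_components == 1L) 2L else 5L,
            nobs = object$n, class = "logLik")
}

#' @param object,newdata `predict` returns the posterior probability that
#'   each score belongs to the high-mean (methylated) component.
#' @rdname fit_two_gaussian_em
#' @export
predict.smalr_mixfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data else as.numeric(newdata)
  d1 <- object$weights[1L] * dnorm_safe(x, object$means[1L], object$sds[1L])
  d2 <- object$weights[2L] * dnorm_safe(x, object$means[2L], object$sds[2L])
  d2 / (d1 + d2)
}

#' @export
simulate.smalr_mixfit <- function(object, nsim = 1L, seed = NULL, ...) {
  draw <- function() {
    comp <- stats::rbinom(object$n, 1L, object$weights[2L]) + 1L
    stats::rnorm(object$n, object$means[comp], object$sds[comp])
  }
  if (is.null(seed)) replicate(nsim, draw(), simplify = FALSE)
  else with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
}

#' @export
plot.smalr_mixfit <- function(x, breaks = 60L, main = "score mixture", ...) {
  if (is.null(x$data)) stop("fit carries no data to plot")
  graphics::hist(x$data, breaks = breaks, freq = FALSE, main = main,
                 xlab = "score", ...)
  xs <- seq(min(x$data), max(x$data), length.out = 400L)
  graphics::lines(xs, x$weights[1L] * stats::dnorm(xs, x$means[1L], x$sds[1L]),
                  col = "steelblue", lwd = 2)
  graphics::lines(xs, x$weights[2L] * stats::dnorm(xs, x$means[2L], x$sds[2L]),
                  col = "firebrick", lwd = 2)
  invisible(x)
}

#' Count density modes of a score distribution
#'
#' Kernel-density mode counting used to describe score distributions as
#' unimodal or bimodal (e.g. phasing analyses): local maxima of
#' `stats::density()` whose height exceeds `min_height` times the global
#' maximum.
#'
#' @param x numeric scores (or a score table).
#' @param adjust bandwidth adjustment passed to `density()`.
#' @param min_height prominence threshold as a fraction of the tallest mode.
#' @return Number of modes (integer), with mode locations as attribute
#'   `locations`.
#' @export
score_modes <- function(x, adjust = 1, min_height = 0.1) {
  if (is.data.frame(x)) x <- x$score
  d <- stats::density(x, adjust = adjust)
  y <- d$y
  is_max <- y > c(-Inf, y[-length(y)]) & y >= c(y[-1L], -Inf)
  keep <- is_max & y >= min_height * max(y)
  structure(sum(keep), locations = d$x[keep])
}
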