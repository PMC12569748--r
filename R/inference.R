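# Log-log transformed pointwise confidence intervals and simultaneous
# confidence bands from bootstrap ensembles.
#
# Transformation: h(x) = log(-log(1 - x)), dh(x) = -1/((1-x) log(1-x)),
# h^{-1}(y) = 1 - exp(-exp(y)).  For x in (0, 1),
# dh(x) = 1 / ((x - 1) log(1 - x)) with positive denominator, so the
# weight g(t) = (est - 1) log(1 - est) / sqrt(n var) satisfies
# g * dh(est) = 1 / sqrt(n var): the weighted, transformed process is the
# studentized realization.

h_loglog <- function(x) log(-log(1 - x))
hinv_loglog <- function(y) 1 - exp(-exp(y))
dh_loglog <- function(x) -1 / ((1 - x) * log(1 - x))

# conservative empirical quantile: the ceiling(B p)-th order statistic
quantile_os <- function(x, p) {
  stopifnot(p > 0, p <= 1)
  sort(x)[ceiling(length(x) * p)]
}

#' Bootstrap variance of the estimator
#'
#' The empirical variance of the bootstrap realizations across replicates
#' (sample variance, denominator `B - 1`), divided by `n`.  Because
#' realizations are stored on the `sqrt(n)` scale for both bootstrap
#' methods, this yields the variance estimate of the CGRFS estimate itself
#' for either method.
#'
#' @param ensemble A [bootstrap_ensemble()] with `B >= 2`.
#' @return A [step_function()] on the ensemble grid (0 before the first
#'   grid point).
#' @export
bootstrap_variance <- function(ensemble) {
  stopifnot(inherits(ensemble, "cgrfs_boot"))
  if (ensemble$B < 2L) stop("variance estimation needs B >= 2")
  mu <- colMeans(ensemble$real)
  v <- (colSums(ensemble$real^2) - ensemble$B * mu^2) / (ensemble$B - 1)
  step_function(ensemble$grid, pmax(v, 0) / ensemble$n, 0)
}

#' Weight function of the transformed confidence band
#'
#' `g(t) = (est(t) - 1) log(1 - est(t)) / sqrt(n var(t))`, evaluated with
#' the estimate clipped to `[0, 1]`.  Time points where the clipped estimate
#' is 0 or 1 or the variance vanishes are flagged degenerate (the
#' transformation is undefined there); they are excluded from band
#' computations rather than raising an error.
#'
#' @param estimate,variance [step_function()]s on a common grid.
#' @param n Number of individuals.
#' @return A [step_function()] on the same grid, `NA` at degenerate points,
#'   with the degeneracy flags attached as attribute `"degenerate"`.
#' @export
weight_g <- function(estimate, variance, n) {
  stopifnot(identical(estimate$times, variance$times))
  est <- pmin(1, pmax(0, estimate$values))
  v <- variance$values
  degen <- est <= 0 | est >= 1 | v <= 0
  g <- rep(NA_real_, length(est))
  g[!degen] <- (est[!degen] - 1) * log(1 - est[!degen]) /
    sqrt(n * v[!degen])
  out <- step_function(estimate$times, g, NA_real_)
  attr(out, "degenerate") <- degen
  out
}

#' Log-log transformed pointwise confidence interval
#'
#' Equal-theta construction on the log-log scale:
#' bounds `1 - (1 - est)^theta` with
#' `theta = exp(+-q / ((est - 1) log(1 - est)))`, where `q` is the
#' `(1 - alpha/2)` empirical quantile of the bootstrap realizations at `t`
#' divided by `sqrt(n)`.  The estimate entering the transformation is
#' clipped to `[0, 1]`; if the clipped estimate is 0 or 1 the interval
#' collapses to the point.
#'
#' @param ensemble A [bootstrap_ensemble()] whose grid covers `t`.
#' @param t Evaluation time(s).
#' @param alpha Significance level (default 0.05 for 95 percent intervals).
#' @param estimate Optional estimate value(s) at `t`; defaults to the
#'   ensemble's stored estimate.
#' @return A data.frame with columns `time`, `estimate` (clipped), `lower`,
#'   `upper`, `q`, `degenerate`.
#' @export
loglog_ci <- function(ensemble, t, alpha = 0.05, estimate = NULL) {
  stopifnot(inherits(ensemble, "cgrfs_boot"), alpha > 0, alpha < 1)
  if (ensemble$B * alpha / 2 < 1)
    warning("B too small for the requested quantile; using the extreme order statistic")
  idx <- findInterval(t, ensemble$grid)
  est <- if (is.null(estimate)) {
    ifelse(idx > 0L, c(0, ensemble$estimate)[idx + 1L], 1)
  } else rep_len(estimate, length(t))
  est <- pmin(1, pmax(0, est))
  out <- data.frame(time = t, estimate = est, lower = est, upper = est,
                    q = 0, degenerate = est <= 0 | est >= 1)
  for (i in seq_along(t)) {
    r <- if (idx[i] > 0L) ensemble$real[, idx[i]] else rep(0, ensemble$B)
    q <- quantile_os(r, 1 - alpha / 2) / sqrt(ensemble$n)
    out$q[i] <- q
    if (!out$degenerate[i]) {
      den <- (est[i] - 1) * log(1 - est[i])
      theta <- exp(c(-1, 1) * q / den)
      bounds <- 1 - (1 - est[i])^theta
      out$lower[i] <- min(bounds)
      out$upper[i] <- max(bounds)
    }
  }
  out
}

#' Quantile of the supremum of the studentized bootstrap process
#'
#' `(1 - alpha)` empirical quantile over replicates of the supremum of
#' `|realization(t)| / sqrt(n var(t))` over the nondegenerate grid points in
#' the band interval (this studentization equals `g(t) dh(est(t)) B(t)` by
#' the algebraic cancellation `g dh = 1/sqrt(n var)`).  The supremum of the
#' step process is attained on jump points, so the evaluation grid is the
#' ensemble grid restricted to the interval plus the two endpoints.
#'
#' @param ensemble A [bootstrap_ensemble()].
#' @param interval Band interval `c(t1, t2)`, `t1 < t2`.
#' @param alpha Significance level.
#' @param variance Optional [bootstrap_variance()] result (recomputed when
#'   `NULL`).
#' @return The quantile, with the evaluation grid (times, column indices and
#'   degeneracy flags) attached as attribute `"eval"`.
#' @export
band_quantile <- function(ensemble, interval, alpha = 0.05, variance = NULL) {
  stopifnot(inherits(ensemble, "cgrfs_boot"),
            length(interval) == 2L, interval[1] < interval[2])
  if (is.null(variance)) variance <- bootstrap_variance(ensemble)
  ev <- band_eval_grid(ensemble, interval, variance)
  use <- !ev$degenerate
  if (!any(use)) stop("no nondegenerate grid point in the band interval")
  idx <- ev$idx[use]
  sd_t <- sqrt(ensemble$n * eval_stepfn(variance, ev$time[use]))
  Cmat <- abs(ensemble$real[, idx, drop = FALSE]) /
    rep(sd_t, each = ensemble$B)
  q <- quantile_os(apply(Cmat, 1L, max), 1 - alpha)
  attr(q, "eval") <- ev
  q
}

# evaluation grid of a band: ensemble grid points inside the interval plus
# the endpoints, with column index into the realization matrix and
# degeneracy flags (clipped estimate in {0, 1} or zero variance)
band_eval_grid <- function(ensemble, interval, variance) {
  g <- ensemble$grid
  tt <- unique(c(interval[1], g[g > interval[1] & g < interval[2]],
                 interval[2]))
  idx <- findInterval(tt, g)
  est <- pmin(1, pmax(0, ifelse(idx > 0L, c(0, ensemble$estimate)[idx + 1L], 1)))
  v <- eval_stepfn(variance, tt)
  data.frame(time = tt, idx = idx,
             estimate = est,
             degenerate = idx == 0L | est <= 0 | est >= 1 | v <= 0)
}

#' Log-log transformed simultaneous confidence band
#'
#' On the log-log scale the band is `h(est(t)) +- q / (sqrt(n) g(t))`,
#' retransformed through `h^{-1}(y) = 1 - exp(-exp(y))`; equivalently the
#' bounds are `1 - (1 - est)^theta` with `theta = exp(+- q sqrt(var) /
#' ((est - 1) log(1 - est)))`.  Bounds lie in `[0, 1]` and contain the
#' clipped estimate; degenerate points carry the collapsed value.
#'
#' @param ensemble A [bootstrap_ensemble()].
#' @param interval Band interval `c(t1, t2)`.
#' @param alpha Significance level.
#' @param q Optional band quantile (computed by [band_quantile()] when
#'   `NULL`).
#' @param variance Optional [bootstrap_variance()] result.
#' @return A data.frame with columns `time`, `estimate` (clipped), `lower`,
#'   `upper`, `degenerate`; the quantile is attached as attribute `"q"`.
#' @export
loglog_band <- function(ensemble, interval, alpha = 0.05, q = NULL,
                        variance = NULL) {
  stopifnot(inherits(ensemble, "cgrfs_boot"))
  if (is.null(variance)) variance <- bootstrap_variance(ensemble)
  if (is.null(q)) q <- band_quantile(ensemble, interval, alpha, variance)
  stopifnot(q >= 0)
  ev <- band_eval_grid(ensemble, interval, variance)
  out <- data.frame(time = ev$time, estimate = ev$estimate,
                    lower = ev$estimate, upper = ev$estimate,
                    degenerate = ev$degenerate)
  use <- !ev$degenerate
  if (any(use)) {
    est <- ev$estimate[use]
    v <- eval_stepfn(variance, ev$time[use])
    half <- as.numeric(q) * sqrt(v) / ((est - 1) * log(1 - est))
    y <- h_loglog(est)
    out$lower[use] <- hinv_loglog(y - half)
    out$upper[use] <- hinv_loglog(y + half)
  }
  attr(out, "q") <- as.numeric(q)
  out
}

#' One-call confidence intervals and bands for CGRFS
#'
#' Convenience wrappers that estimate chronic GvHD- and relapse-free
#' survival, run the requested bootstrap and return log-log transformed
#' pointwise confidence intervals ([cgrfs_ci()]) or a simultaneous
#' confidence band ([cgrfs_band()]).
#'
#' @param dataset An [msm_dataset()] (progressive six-state; mapped down
#'   automatically for `estimator = "aje_idm3"`).
#' @param estimator One of `"km_comb"`, `"aje_prog6"`, `"aje_idm3"`.
#' @param method Bootstrap method, `"wild"` or `"efron"`.
#' @param t Time point(s) for the interval(s).
#' @param B Number of bootstrap replicates.
#' @param alpha Significance level.
#' @param seed Optional integer seed.
#' @return A data.frame of bounds (see [loglog_ci()] / [loglog_band()]).
#' @export
cgrfs_ci <- function(dataset, estimator = "km_comb", method = "wild",
                     t, B = 1000L, alpha = 0.05, seed = NULL) {
  ens <- bootstrap_ensemble(dataset, estimator, method, B = B, seed = seed,
                            times = t)
  loglog_ci(ens, t, alpha)
}

#' @param interval Band interval `c(t1, t2)`.
#' @rdname cgrfs_ci
#' @export
cgrfs_band <- function(dataset, estimator = "km_comb", method = "wild",
                       interval, B = 1000L, alpha = 0.05, seed = NULL) {
  ens <- bootstrap_ensemble(dataset, estimator, method, B = B, seed = seed)
  loglog_band(ens, interval, alpha)
}
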