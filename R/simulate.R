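#' Simulation configuration for the non-Markov frailty scenario
#'
#' Study conditions of the coverage experiments: constant per-day baseline
#' hazards on the progressive six-state chain, each multiplied by an
#' individual gamma frailty `Z ~ Gamma(shape 2, scale 1)` (mean 2,
#' variance 2), and independent exponential right-censoring.  The frailty
#' makes the marginal process non-Markov while keeping the conditional
#' sojourn times exponential.
#'
#' @param n Number of individuals.
#' @param hazards Named per-day baseline hazards for the nine transitions.
#' @param frailty_shape,frailty_scale Gamma frailty parameters.
#' @param cens_rate Rate of the exponential censoring time (per day);
#'   must be strictly positive.
#' @param censoring Logical: disable to simulate without right-censoring
#'   (all paths then end in death/relapse).
#' @return An object of class `cgrfs_simconfig`.
#' @export
sim_config <- function(n = 200L,
                       hazards = c(a01 = 0.0009, a12 = 0.0008,
                                   a23 = 0.001, a34 = 0.00065,
                                   a05 = 0.00075, a15 = 0.0006,
                                   a25 = 0.0006, a35 = 0.0006,
                                   a45 = 0.0006),
                       frailty_shape = 2, frailty_scale = 1,
                       cens_rate = 0.00095, censoring = TRUE) {
  need <- c("a01", "a12", "a23", "a34", "a05", "a15", "a25", "a35", "a45")
  if (!all(need %in% names(hazards)))
    stop("hazards must name all nine transitions: ",
         paste(need, collapse = ", "))
  hazards <- hazards[need]
  stopifnot(all(hazards > 0), frailty_shape > 0, frailty_scale > 0)
  if (!is.finite(cens_rate) || cens_rate <= 0)
    stop("cens_rate must be a finite positive rate; ",
         "disable censoring with censoring = FALSE instead")
  structure(list(n = as.integer(n), hazards = hazards,
                 frailty_shape = frailty_shape,
                 frailty_scale = frailty_scale,
                 cens_rate = cens_rate, censoring = isTRUE(censoring)),
            class = "cgrfs_simconfig")
}

#' @export
print.cgrfs_simconfig <- function(x, ...) {
  cat(sprintf("<cgrfs_simconfig>: n=%d, frailty Gamma(%g, scale %g), %s\n",
              x$n, x$frailty_shape, x$frailty_scale,
              if (x$censoring) sprintf("censoring Exp(%g)", x$cens_rate)
              else "no censoring"))
  cat("  hazards:", paste(sprintf("%s=%g", names(x$hazards), x$hazards),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Simulate the progressive six-state model with gamma frailty
#'
#' Per individual a frailty `Z` is drawn; given `Z`, the chain starts in
#' state 0 and from each transient state `g` waits an exponential time with
#' rate `Z * (a_{g,g+1} + a_{g,5})`, then moves to `g+1` or to death/relapse
#' 5 with the proportional probabilities (state 4 can only move to 5).
#' Censoring is an independent `Exp(cens_rate)` time; records are emitted up
#' to the minimum of absorption and censoring.  Marginally (after
#' integrating the frailty out) the process is non-Markov.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; the calling RNG state is restored.
#' @param frailty Optional vector of frailty values to use instead of fresh
#'   gamma draws (mainly for testing conditional properties).
#' @return An [msm_dataset()] under the progressive six-state model.
#' @export
simulate_prog6 <- function(config, seed = NULL, frailty = NULL) {
  stopifnot(inherits(config, "cgrfs_simconfig"))
  n <- config$n
  a <- config$hazards
  anext <- c(a[["a01"]], a[["a12"]], a[["a23"]], a[["a34"]], 0)
  adeath <- c(a[["a05"]], a[["a15"]], a[["a25"]], a[["a35"]], a[["a45"]])
  with_seed_(seed, {
    Z <- if (is.null(frailty))
      stats::rgamma(n, shape = config$frailty_shape,
                    scale = config$frailty_scale)
    else rep_len(frailty, n)
    C <- if (config$censoring) stats::rexp(n, config$cens_rate)
         else rep(Inf, n)
    # stage-wise waiting times and destinations (TRUE = progress to g+1)
    ct <- matrix(0, n, 5L)       # transition times out of states 0..4
    prog <- matrix(FALSE, n, 5L)
    tprev <- numeric(n)
    for (g in 1:5) {
      tot <- Z * (anext[g] + adeath[g])
      ct[, g] <- tprev + stats::rexp(n, tot)
      prog[, g] <- stats::runif(n) < anext[g] / (anext[g] + adeath[g])
      tprev <- ct[, g]
    }
    # number of progressions before death: leading TRUEs of each row
    cp <- prog[, 1L]
    stages <- as.integer(cp)
    for (g in 2:5) {
      cp <- cp & prog[, g]
      stages <- stages + cp
    }
    death_time <- ct[cbind(seq_len(n), stages + 1L)]

    id <- integer(0); from <- integer(0); to <- integer(0); tm <- numeric(0)
    for (g in 1:4) {   # progression g-1 -> g
      sel <- stages >= g & ct[, g] <= C
      id <- c(id, which(sel))
      from <- c(from, rep(g - 1L, sum(sel)))
      to <- c(to, rep(g, sum(sel)))
      tm <- c(tm, ct[sel, g])
    }
    sel <- death_time <= C
    id <- c(id, which(sel))
    from <- c(from, stages[sel])
    to <- c(to, rep(5L, sum(sel)))
    tm <- c(tm, death_time[sel])
    # censoring records for everyone not absorbed by C
    sel <- death_time > C
    if (any(sel)) {
      # state at C- : number of observed progressions
      nprog <- integer(n)
      for (g in 1:4) nprog <- nprog + as.integer(stages >= g & ct[, g] <= C)
      id <- c(id, which(sel))
      from <- c(from, nprog[sel])
      to <- c(to, rep(NA_integer_, sum(sel)))
      tm <- c(tm, C[sel])
    }
    ev <- data.frame(id = as.character(id), from = from, to = to, time = tm)
    ev <- ev[order(id, tm), , drop = FALSE]
    rownames(ev) <- NULL
    ds <- new_msm_dataset(ev, model_prog6())
    attr(ds, "frailty") <- Z
    attr(ds, "cens_time") <- C
    ds
  })
}

#' Approximate the true CGRFS curve
#'
#' The true chronic GvHD- and relapse-free survival under a simulation
#' configuration is approximated by the empirical proportion of individuals
#' in states `{0, 2, 4}` in a large uncensored simulated cohort (on
#' uncensored data this coincides exactly with the Aalen-Johansen estimate
#' in the progressive model).
#'
#' @param config A [sim_config()] (its censoring settings are ignored; the
#'   truth cohort is always uncensored).
#' @param n_truth Size of the truth cohort.
#' @param seed Optional integer seed.
#' @return A [step_function()] starting at 1.
#' @export
approximate_truth <- function(config, n_truth = 200000L, seed = NULL) {
  stopifnot(n_truth >= 1L)
  cfg <- config
  cfg$n <- as.integer(n_truth)
  cfg$censoring <- FALSE
  ds <- simulate_prog6(cfg, seed = seed)
  ev <- ds$events
  # membership of {0, 2, 4} changes only at some transitions
  member <- c(1L, 0L, 1L, 0L, 1L, 0L)
  delta <- member[ev$to + 1L] - member[ev$from + 1L]
  keep <- delta != 0L
  o <- order(ev$time[keep])
  tt <- ev$time[keep][o]
  val <- 1 + cumsum(delta[keep][o]) / n_truth
  last <- !duplicated(tt, fromLast = TRUE)   # ties: keep final value
  step_function(tt[last], val[last], 1)
}

#' Frequency of out-of-bounds Kaplan-Meier combination estimates
#'
#' Simulates `reps` datasets under a configuration and counts in how many
#' the unclipped Kaplan-Meier combination attains a strictly negative value
#' at some observed time, and in how many it exceeds one.
#'
#' @param config A [sim_config()].
#' @param reps Number of simulated datasets.
#' @param seed Integer master seed (one substream per replicate).
#' @return A list with `negative`, `greater_one` (counts) and `reps`.
#' @export
oob_frequency <- function(config, reps, seed = 1L) {
  neg <- 0L
  gt1 <- 0L
  for (r in seq_len(reps)) {
    ds <- simulate_prog6(config, seed = replicate_seed(seed, r))
    v <- cgrfs_km(ds)$values
    if (any(v < 0)) neg <- neg + 1L
    if (any(v > 1)) gt1 <- gt1 + 1L
  }
  list(negative = neg, greater_one = gt1, reps = reps)
}

# deterministic per-replicate substream seed (kept below 2^31)
replicate_seed <- function(master, r) {
  as.integer((as.numeric(master) * 48271 + r * 7919) %% 2147483629)
}

#' Coverage experiment for confidence intervals and bands
#'
#' For each replicate a dataset is simulated from the configuration, the
#' requested CGRFS estimators are computed, bootstrap ensembles of size `B`
#' are generated for each requested method, and log-log transformed
#' pointwise confidence intervals (at `ci_times`) and simultaneous
#' confidence bands (over `band_intervals`) are constructed.  Coverage is
#' the proportion of replicates whose interval (respectively band, at every
#' nondegenerate evaluation point) contains the true curve approximated by
#' [approximate_truth()].  Replicates where the clipped estimate is
#' degenerate at a requested CI time count as covered only if the truth
#' equals the collapsed point.  Out-of-bounds occurrences of the unclipped
#' Kaplan-Meier combination are recorded per replicate.
#'
#' The experiment is fully seeded: each replicate runs on its own
#' deterministic substream of the master seed, so any subset of replicates
#' can be reproduced independently.
#'
#' @param config A [sim_config()].
#' @param reps Number of simulation replicates.
#' @param B Bootstrap replicates per dataset and method.
#' @param ci_times Time points for pointwise confidence intervals.
#' @param band_intervals List of band intervals `c(t1, t2)`; `NULL` for no
#'   bands.
#' @param estimators Estimators to evaluate (subset of `"km_comb"`,
#'   `"aje_prog6"`, `"aje_idm3"`).
#' @param methods Bootstrap methods (subset of `"wild"`, `"efron"`).
#' @param band_estimators,band_methods Subsets for which bands are computed
#'   (defaults: same as `estimators` / `methods`).
#' @param alpha Significance level.
#' @param seed Integer master seed.
#' @param truth Optional [approximate_truth()] step function; computed from
#'   `config` with `n_truth` individuals when `NULL`.
#' @param n_truth Truth cohort size when `truth` is `NULL`.
#' @return A data.frame of class `cgrfs_coverage` with one row per
#'   (estimator, method, target): columns `n`, `estimator`, `method`,
#'   `type` (`"ci"` or `"band"`), `target`, `covered`, `reps`, `coverage`,
#'   `B`.  Out-of-bounds counts are attached as attribute `"oob"`.
#' @export
coverage_experiment <- function(config, reps, B,
                                ci_times = c(500, 750, 1000, 2000),
                                band_intervals = list(c(0, 2000), c(10, 2000)),
                                estimators = c("km_comb", "aje_prog6", "aje_idm3"),
                                methods = c("wild", "efron"),
                                band_estimators = estimators,
                                band_methods = methods,
                                alpha = 0.05, seed = 1L,
                                truth = NULL, n_truth = 200000L) {
  stopifnot(inherits(config, "cgrfs_simconfig"), reps >= 1L, B >= 2L)
  estimators <- match.arg(estimators, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(truth))
    truth <- approximate_truth(config, n_truth,
                               seed = replicate_seed(seed, 0L))
  band_labels <- vapply(band_intervals, function(iv)
    sprintf("[%g,%g]", iv[1], iv[2]), character(1))

  tasks <- expand.grid(estimator = estimators, method = methods,
                       stringsAsFactors = FALSE)
  ci_cov <- array(0L, c(nrow(tasks), length(ci_times)))
  band_cov <- array(0L, c(nrow(tasks), length(band_intervals)))
  band_on <- tasks$estimator %in% band_estimators &
    tasks$method %in% band_methods
  oob_neg <- 0L
  oob_gt1 <- 0L

  for (r in seq_len(reps)) {
    res <- with_seed_(replicate_seed(seed, r), {
      ds <- simulate_prog6(config)
      replicate_inference(ds, tasks, band_on, B, ci_times, band_intervals,
                          alpha, truth)
    })
    ci_cov <- ci_cov + res$ci
    band_cov <- band_cov + res$band
    oob_neg <- oob_neg + res$oob[1L]
    oob_gt1 <- oob_gt1 + res$oob[2L]
  }

  rows <- list()
  for (i in seq_len(nrow(tasks))) {
    if (length(ci_times))
      rows[[length(rows) + 1L]] <- data.frame(
        n = config$n, estimator = tasks$estimator[i],
        method = tasks$method[i], type = "ci",
        target = as.character(ci_times), covered = ci_cov[i, ],
        reps = reps, coverage = ci_cov[i, ] / reps, B = B)
    if (band_on[i] && length(band_intervals))
      rows[[length(rows) + 1L]] <- data.frame(
        n = config$n, estimator = tasks$estimator[i],
        method = tasks$method[i], type = "band",
        target = band_labels, covered = band_cov[i, ],
        reps = reps, coverage = band_cov[i, ] / reps, B = B)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "oob") <- c(negative = oob_neg, greater_one = oob_gt1)
  class(out) <- c("cgrfs_coverage", "data.frame")
  out
}

# inference on a single simulated dataset: returns CI / band containment
# indicators for every task, plus out-of-bounds flags.  Uses the current
# RNG stream.
replicate_inference <- function(ds, tasks, band_on, B, ci_times,
                                band_intervals, alpha, truth) {
  cnt <- build_counting(ds)
  est_km <- cgrfs_km(cnt)
  cnt_idm <- NULL
  needs_idm <- any(tasks$estimator == "aje_idm3")
  if (needs_idm) cnt_idm <- build_counting(map_prog6_to_idm3_fast(ds))

  oob <- c(any(est_km$values < 0), any(est_km$values > 1))

  estimates <- list()
  if (any(tasks$estimator == "km_comb")) estimates$km_comb <- est_km
  if (any(tasks$estimator == "aje_prog6"))
    estimates$aje_prog6 <- cgrfs_aje(cnt)
  if (needs_idm) estimates$aje_idm3 <- cgrfs_aje(cnt_idm)

  efron_need <- unique(tasks$estimator[tasks$method == "efron"])
  efron_real <- NULL
  if (length(efron_need)) {
    grid_ef <- sort(unique(c(cnt$times, ci_times)))
    efron_real <- efron_realizations_multi(ds, efron_need, grid_ef, B)
  }

  ci <- matrix(0L, nrow(tasks), length(ci_times))
  band <- matrix(0L, nrow(tasks), length(band_intervals))
  for (i in seq_len(nrow(tasks))) {
    est_name <- tasks$estimator[i]
    estf <- estimates[[est_name]]
    if (tasks$method[i] == "wild") {
      cc <- if (est_name == "aje_idm3") cnt_idm else cnt
      W <- switch(est_name,
        km_comb = wild_km_coef(cc, attr(est_km, "components")),
        aje_prog6 = wild_aje_coef(cc, c(0L, 2L, 4L)),
        aje_idm3 = wild_aje_coef(cc, 0L))
      G <- matrix(stats::rnorm(B * nrow(cc$jumps)), nrow = B)
      ens <- structure(list(method = "wild", estimator = est_name,
                            n = cnt$n, B = B, grid = cc$times,
                            estimate = estf$values, real = G %*% W),
                       class = "cgrfs_boot")
    } else {
      grid_ef <- sort(unique(c(cnt$times, ci_times)))
      ens <- structure(list(method = "efron", estimator = est_name,
                            n = cnt$n, B = B, grid = grid_ef,
                            estimate = eval_stepfn(estf, grid_ef),
                            real = efron_real[[est_name]]),
                       class = "cgrfs_boot")
    }
    if (length(ci_times)) {
      res <- loglog_ci(ens, ci_times, alpha)
      tv <- eval_stepfn(truth, ci_times)
      ok <- ifelse(res$degenerate,
                   abs(tv - res$estimate) < 1e-12,
                   res$lower <= tv & tv <= res$upper)
      ci[i, ] <- as.integer(ok)
    }
    if (band_on[i] && length(band_intervals)) {
      v <- bootstrap_variance(ens)
      for (bi in seq_along(band_intervals)) {
        iv <- band_intervals[[bi]]
        bq <- try(band_quantile(ens, iv, alpha, v), silent = TRUE)
        if (inherits(bq, "try-error")) next   # no usable grid point
        bd <- loglog_band(ens, iv, alpha, q = bq, variance = v)
        use <- !bd$degenerate
        tv <- eval_stepfn(truth, bd$time[use])
        band[i, bi] <- as.integer(all(bd$lower[use] <= tv &
                                      tv <= bd$upper[use]))
      }
    }
  }
  list(ci = ci, band = band, oob = as.integer(oob))
}

#' @export
print.cgrfs_coverage <- function(x, ...) {
  cat(sprintf("<cgrfs_coverage>: n=%d, %d replicates, B=%d\n",
              x$n[1], x$reps[1], x$B[1]))
  print.data.frame(x, row.names = FALSE)
  oob <- attr(x, "oob")
  if (!is.null(oob))
    cat(sprintf("out-of-bounds KM combination: %d negative, %d > 1 (of %d)\n",
                oob[1], oob[2], x$reps[1]))
  invisible(x)
}
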