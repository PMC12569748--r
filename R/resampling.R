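# Wild bootstrap (multiplier resampling of the Nelson-Aalen martingale
# increments) and Efron's bootstrap (resampling individuals).

# evaluate `code` under a temporary seed, restoring the RNG state afterwards
with_seed_ <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    )
  }
  code
}

#' Wild bootstrap multipliers
#'
#' Draws one independent standard normal multiplier per observed individual
#' transition (per individual, transition type and jump time).  In the
#' illness-death model with recovery an individual's recurrent 0->1
#' episodes therefore receive independent draws; in the progressive model
#' each individual transition type jumps at most once.
#'
#' @param counting A [build_counting()] object (its jump registry determines
#'   the number of draws).
#' @param B Number of multiplier sets to draw.
#' @param seed Optional integer seed; the calling RNG state is restored
#'   afterwards.
#' @return A `B x E` matrix, `E` the number of individual jumps; the jump
#'   registry is attached as attribute `"jumps"`.
#' @export
draw_multipliers <- function(counting, B = 1L, seed = NULL) {
  stopifnot(inherits(counting, "msm_counting"), B >= 1L)
  E <- nrow(counting$jumps)
  G <- with_seed_(seed, matrix(stats::rnorm(B * E), nrow = B))
  attr(G, "jumps") <- counting$jumps
  G
}

#' Multiplier process of the Nelson-Aalen deviation
#'
#' The wild bootstrap counterpart of `sqrt(n) (A_hat - A)`: at each
#' individual g->h jump the off-diagonal entry `xi_gh` jumps by
#' `sqrt(n) G / Y_g(t-)`, with `G` the jump's multiplier; diagonal entries
#' keep the row sums at zero.  Given the data, `xi` shares the limit
#' distribution of the Nelson-Aalen deviation process.
#'
#' @param counting A [build_counting()] object.
#' @param multipliers A numeric vector with one multiplier per row of
#'   `counting$jumps` (e.g. one row of [draw_multipliers()]).
#' @return An object of class `msm_cumhaz` holding the increments and the
#'   cumulative process.
#' @export
xi_process <- function(counting, multipliers) {
  stopifnot(inherits(counting, "msm_counting"))
  j <- counting$jumps
  multipliers <- as.numeric(multipliers)
  stopifnot(length(multipliers) == nrow(j))
  K <- counting$model$K
  m <- length(counting$times)
  dXi <- array(0, c(K, K, m))
  if (nrow(j) > 0L) {
    val <- sqrt(counting$n) * multipliers / j$Yfrom
    off <- (j$from + 1L) + K * j$to + K * K * (j$k - 1L)
    dia <- (j$from + 1L) + K * j$from + K * K * (j$k - 1L)
    agg <- rowsum(c(val, -val), c(off, dia))
    dXi[as.integer(rownames(agg))] <- agg
  }
  Xi <- dXi
  if (m > 1L) Xi <- aperm(apply(dXi, c(1, 2), cumsum), c(2, 3, 1))
  structure(list(model = counting$model, n = counting$n,
                 times = counting$times, dA = dXi, A = Xi),
            class = "msm_cumhaz")
}

#' Wild bootstrap realization for the Kaplan-Meier combination
#'
#' One realization of the limit process of
#' `sqrt(n) {CGRFS_hat(t) - CGRFS(t)}` for the five-Kaplan-Meier
#' combination, obtained by pushing the multiplier process through the
#' Hadamard derivative of each component: the derivative of component `j`
#' in direction `xi` is `-S_j(t) * I_j(t)` with
#' `I_j(t) = sum_{s <= t} u_j(s)' dxi(s) v_j(s)`, and the realization is the
#' signed combination `-S1 I1 - S2 I2 + S3 I3 - S4 I4 + S5 I5`.  In a
#' pure-survival reduction (only 0->5 transitions) this collapses to the
#' classical Kaplan-Meier wild bootstrap `-S_hat(t) xi_05(t)`.
#'
#' @param counting A [build_counting()] object under the progressive
#'   six-state model.
#' @param xi An [xi_process()] built from the same counting system.
#' @param components Optional list of the five [km_component()] step
#'   functions (recomputed when `NULL`).
#' @return A [step_function()] on the counting grid (value 0 before the
#'   first event).
#' @export
wild_km_realization <- function(counting, xi, components = NULL) {
  stopifnot(inherits(counting, "msm_counting"), inherits(xi, "msm_cumhaz"))
  if (counting$model$name != "prog6")
    stop("the Kaplan-Meier combination requires the progressive six-state model")
  if (!identical(counting$times, xi$times))
    stop("counting system and xi process are on different grids")
  m <- length(counting$times)
  if (m == 0L) return(step_function(numeric(), numeric(), 0))
  if (is.null(components))
    components <- lapply(1:5, function(j) km_component(counting, km_spec(j)))
  sgn <- c(-1, -1, 1, -1, 1)
  val <- numeric(m)
  for (j in 1:5) {
    sp <- km_spec(j)
    YR <- rowSums(counting$Y[, sp$risk + 1L, drop = FALSE])
    dI <- numeric(m)
    for (g in sp$risk) {
      w <- ifelse(YR > 0, counting$Y[, g + 1L] / YR, 0)
      dcontrib <- colSums(matrix(xi$dA[g + 1L, sp$targets + 1L, ],
                                 nrow = length(sp$targets)))
      dI <- dI + w * dcontrib
    }
    val <- val + sgn[j] * components[[j]]$values * cumsum(dI)
  }
  step_function(counting$times, val, 0)
}

#' Wild bootstrap realization for an Aalen-Johansen functional
#'
#' One realization of the limit process of the centered, root-n scaled
#' Aalen-Johansen functional: the matrix-valued direction
#' `D(t) = sum_{s <= t} P(0, s-) dxi(s) P(s, t)` is accumulated by the
#' forward recursion `D_k = D_{k-1} (I + dA_k) + P(0, t_{k-1}) dxi_k`, and
#' the row-0 entries are summed over the functional's state set.  Row sums
#' of `D(t)` are zero at every time.
#'
#' @param counting A [build_counting()] object.
#' @param xi An [xi_process()] built from the same counting system.
#' @param states Functional state set (default: the CGRFS states of the
#'   model, `{0, 2, 4}` for the progressive model, `{0}` for the
#'   illness-death model).
#' @param full Return the full matrix path `D` (a `K x K x m` array) as
#'   attribute `"D"`?
#' @return A [step_function()] (value 0 before the first event).
#' @export
wild_aje_realization <- function(counting, xi, states = NULL, full = FALSE) {
  stopifnot(inherits(counting, "msm_counting"), inherits(xi, "msm_cumhaz"))
  if (!identical(counting$times, xi$times))
    stop("counting system and xi process are on different grids")
  K <- counting$model$K
  if (is.null(states)) states <- cgrfs_states(counting$model)
  if (!all(states %in% 0:(K - 1L)))
    stop("functional states outside the model's state space")
  m <- length(counting$times)
  if (m == 0L) return(step_function(numeric(), numeric(), 0))
  dA <- nelson_aalen(counting)$dA
  D <- matrix(0, K, K)
  P <- diag(K)
  I <- diag(K)
  val <- numeric(m)
  Dfull <- if (full) array(0, c(K, K, m)) else NULL
  for (k in seq_len(m)) {
    step <- I + dA[, , k]
    D <- D %*% step + P %*% xi$dA[, , k]
    P <- P %*% step
    val[k] <- sum(D[1L, states + 1L])
    if (full) Dfull[, , k] <- D
  }
  out <- step_function(counting$times, val, 0)
  if (full) attr(out, "D") <- Dfull
  out
}

#' Efron bootstrap resample
#'
#' Draws `n` individuals independently and uniformly with replacement from
#' the dataset and copies their whole observed paths under fresh ids.
#' Valid under an i.i.d. data structure, i.e. random censoring.
#'
#' @param dataset An [msm_dataset()] with at least one individual.
#' @param seed Optional integer seed; the calling RNG state is restored.
#' @return An [msm_dataset()] with `n` (possibly duplicated) paths.
#' @export
efron_resample <- function(dataset, seed = NULL) {
  stopifnot(inherits(dataset, "msm_dataset"))
  if (dataset$n < 1L) stop("cannot resample an empty dataset")
  with_seed_(seed, {
    ids <- unique(dataset$events$id)
    rows_by_id <- split(seq_len(nrow(dataset$events)), dataset$events$id)[ids]
    pick <- sample.int(length(ids), length(ids), replace = TRUE)
    take <- rows_by_id[pick]
    ev <- dataset$events[unlist(take, use.names = FALSE), , drop = FALSE]
    ev$id <- rep(as.character(seq_along(pick)), lengths(take))
    rownames(ev) <- NULL
    new_msm_dataset(ev, dataset$model)
  })
}

# internal: dataset constructor bypassing validation (inputs known valid)
new_msm_dataset <- function(events, model) {
  structure(list(model = model, events = events,
                 n = length(unique(events$id))),
            class = "msm_dataset")
}

#' Bootstrap ensemble of centered CGRFS realizations
#'
#' Generates `B` bootstrap realizations of the centered estimator process on
#' a shared time grid, stored on the `sqrt(n)`-difference scale for both
#' methods: wild realizations approximate
#' `sqrt(n) {CGRFS_hat(t) - CGRFS(t)}` directly, while Efron realizations
#' are `sqrt(n) {CGRFS*_hat(t) - CGRFS_hat(t)}` from re-estimation on
#' resampled individuals.  For the Kaplan-Meier combination under Efron's
#' bootstrap both the resampled and the original estimate are clipped to
#' `[0, 1]` before centering; wild realizations are never clipped.
#'
#' @param dataset An [msm_dataset()].  For `km_comb` and `aje_prog6` it must
#'   be under the progressive six-state model; for `aje_idm3` a progressive
#'   dataset is mapped down automatically.
#' @param estimator One of `"km_comb"`, `"aje_prog6"`, `"aje_idm3"`.
#' @param method `"wild"` or `"efron"`.
#' @param B Number of bootstrap replicates (at least 1).
#' @param seed Optional integer seed.
#' @param times Optional evaluation times; by default realizations are
#'   stored on the estimate's full jump-time grid.
#' @param multipliers Optional `B x E` matrix of wild multipliers to use
#'   instead of fresh standard normal draws (wild method only; mainly for
#'   testing).
#' @param details Attach the coefficient matrix and multipliers (wild) as
#'   attributes?
#' @return An object of class `cgrfs_boot`: list with fields `method`,
#'   `estimator`, `n`, `B`, `grid`, `estimate` (estimate values on the
#'   grid; for `km_comb` the unclipped values), and `real`
#'   (`B x length(grid)` realization matrix).
#' @export
bootstrap_ensemble <- function(dataset,
                               estimator = c("km_comb", "aje_prog6", "aje_idm3"),
                               method = c("wild", "efron"),
                               B = 1000L, seed = NULL, times = NULL,
                               multipliers = NULL, details = FALSE) {
  estimator <- match.arg(estimator)
  method <- match.arg(method)
  stopifnot(inherits(dataset, "msm_dataset"), B >= 1L)
  if (estimator %in% c("km_comb", "aje_prog6") &&
      dataset$model$name != "prog6")
    stop(sprintf("estimator '%s' requires a progressive six-state dataset",
                 estimator))
  if (estimator == "aje_idm3" && dataset$model$name == "prog6")
    dataset <- map_prog6_to_idm3(dataset)
  counting <- build_counting(dataset)
  grid_full <- counting$times
  if (is.null(times)) {
    grid <- grid_full
    gidx <- seq_along(grid_full)
  } else {
    grid <- sort(as.numeric(times))
    gidx <- findInterval(grid, grid_full)   # 0 = before first event
  }

  est_full <- switch(estimator,
    km_comb = cgrfs_km(counting),
    cgrfs_aje(counting))
  est_grid <- if (length(grid)) eval_stepfn(est_full, grid) else numeric()

  real <- with_seed_(seed, {
    if (method == "wild") {
      G <- if (is.null(multipliers))
        matrix(stats::rnorm(B * nrow(counting$jumps)), nrow = B)
      else {
        stopifnot(nrow(multipliers) == B,
                  ncol(multipliers) == nrow(counting$jumps))
        multipliers
      }
      W <- switch(estimator,
        km_comb = wild_km_coef(counting),
        wild_aje_coef(counting, cgrfs_states(counting$model)))
      R <- G %*% W   # B x m on the full grid
      out <- matrix(0, B, length(grid))
      pos <- gidx > 0L
      out[, pos] <- R[, gidx[pos], drop = FALSE]
      if (details) {
        attr(out, "W") <- W
        attr(out, "multipliers") <- G
      }
      out
    } else {
      efron_realizations(dataset, estimator, grid, B)
    }
  })
  structure(list(method = method, estimator = estimator,
                 n = counting$n, B = B, grid = grid,
                 estimate = est_grid, real = real),
            class = "cgrfs_boot")
}

#' @export
print.cgrfs_boot <- function(x, ...) {
  cat(sprintf("<cgrfs_boot>: %s bootstrap, estimator %s, n=%d, B=%d, %d grid points\n",
              x$method, x$estimator, x$n, x$B, length(x$grid)))
  invisible(x)
}

# ---- internal fast paths ----------------------------------------------------

# coefficient matrix W (E jumps x m grid) of the wild realization for the
# KM combination: realizations = G %*% W.  Per jump e in risk set R_j with
# target state h, component j contributes sgn_j * S_j(t) * sqrt(n)/Y_Rj(t_e-)
# for all grid times t >= t_e.
wild_km_coef <- function(counting, components = NULL) {
  m <- length(counting$times)
  j <- counting$jumps
  E <- nrow(j)
  W <- matrix(0, E, m)
  if (E == 0L || m == 0L) return(W)
  if (is.null(components))
    components <- lapply(1:5, function(jj) km_component(counting, km_spec(jj)))
  sgn <- c(-1, -1, 1, -1, 1)
  sqn <- sqrt(counting$n)
  mask <- outer(j$k, seq_len(m), "<=")
  for (jj in 1:5) {
    sp <- km_spec(jj)
    YR <- rowSums(counting$Y[, sp$risk + 1L, drop = FALSE])
    inj <- j$from %in% sp$risk & j$to %in% sp$targets
    if (!any(inj)) next
    ce <- numeric(E)
    ce[inj] <- sqn / YR[j$k[inj]]
    W <- W + (mask * ce) * rep(sgn[jj] * components[[jj]]$values,
                               each = E)
  }
  W
}

# coefficient matrix W (E x m) of the wild realization for an
# Aalen-Johansen functional over `states`; realizations = G %*% W.
wild_aje_coef <- function(counting, states) {
  m <- length(counting$times)
  j <- counting$jumps
  E <- nrow(j)
  if (E == 0L || m == 0L) return(matrix(0, E, m))
  K <- counting$model$K
  dA <- nelson_aalen(counting)$dA
  row0 <- prodint_row_cpp(dA, 0L)          # m x K, row-0 prefixes
  # P(0, t_{k-1})[0, g] with P(0, t_0) = I
  aprev <- rbind(c(1, rep(0, K - 1L)), row0)[j$k, , drop = FALSE]
  a <- sqrt(counting$n) / j$Yfrom * aprev[cbind(seq_len(E), j$from + 1L)]
  f <- numeric(K)
  f[states + 1L] <- 1
  aje_wild_coef_cpp(dA, f, as.integer(j$k), as.integer(j$from),
                    as.integer(j$to), a, as.integer(seq_len(m)))
}

# Efron realizations sqrt(n) (est* - est) for one estimator at grid times;
# uses the current RNG stream.
efron_realizations <- function(dataset, estimator, grid, B) {
  out <- efron_realizations_multi(dataset, estimator, grid, B)
  out[[estimator]]
}

# fast prog6 -> idm3 path mapping without re-validation (inputs known valid)
map_prog6_to_idm3_fast <- function(dataset) {
  statemap <- c(0L, 1L, 0L, 1L, 0L, 2L)
  ev <- dataset$events
  ev$from <- statemap[ev$from + 1L]
  obs <- !is.na(ev$to)
  ev$to[obs] <- statemap[ev$to[obs] + 1L]
  new_msm_dataset(ev, model_idm3())
}

# shared-resample Efron realizations for several estimators at once.
# `dataset` must be prog6 if any estimator needs it; aje_idm3 is computed
# on the mapped paths of the same resampled individuals.
efron_realizations_multi <- function(dataset, estimators, grid, B) {
  stopifnot(dataset$n >= 1L)
  sqn <- sqrt(dataset$n)
  need_prog <- any(estimators %in% c("km_comb", "aje_prog6"))
  if (dataset$model$name == "idm3" && need_prog)
    stop("progressive-model estimators need a progressive dataset")

  # estimates of all requested estimators at the grid times, building each
  # counting system once
  all_est <- function(ds) {
    out <- list()
    if (need_prog) {
      cnt <- build_counting(ds)
      if ("km_comb" %in% estimators)
        out$km_comb <- eval_stepfn(clip_unit(cgrfs_km(cnt)), grid)
      if ("aje_prog6" %in% estimators)
        out$aje_prog6 <- eval_stepfn(cgrfs_aje(cnt), grid)
    }
    if ("aje_idm3" %in% estimators) {
      dsi <- if (ds$model$name == "prog6") map_prog6_to_idm3_fast(ds) else ds
      out$aje_idm3 <- eval_stepfn(cgrfs_aje(build_counting(dsi)), grid)
    }
    out
  }
  orig <- all_est(dataset)

  ev <- dataset$events
  ids <- unique(ev$id)
  rows_by_id <- split(seq_len(nrow(ev)), ev$id)[ids]
  out <- lapply(stats::setNames(estimators, estimators),
                function(w) matrix(0, B, length(grid)))
  for (b in seq_len(B)) {
    pick <- sample.int(length(ids), length(ids), replace = TRUE)
    take <- rows_by_id[pick]
    evb <- ev[unlist(take, use.names = FALSE), , drop = FALSE]
    evb$id <- rep.int(seq_along(pick), lengths(take))
    estb <- all_est(new_msm_dataset(evb, dataset$model))
    for (w in estimators)
      out[[w]][b, ] <- sqn * (estb[[w]] - orig[[w]])
  }
  out
}
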