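#' Nelson-Aalen estimator of the cumulative transition rates
#'
#' At every observed transition time `t` the off-diagonal increment is
#' `dN_gh(t) / Y_g(t-)` (zero when no one is at risk); diagonal entries are
#' set so that every row of the increment matrix sums to zero.  Tied
#' transitions at one time contribute a single aggregated increment.  The
#' estimator is consistent for the partly conditional cumulative transition
#' rates even without a Markov assumption, provided censoring is random.
#'
#' @param counting An [build_counting()] object.
#' @return An object of class `msm_cumhaz`: list with `times`, the increment
#'   array `dA` (`K x K x m`) and the cumulative array `A`.
#' @export
nelson_aalen <- function(counting) {
  stopifnot(inherits(counting, "msm_counting"))
  K <- counting$model$K
  m <- length(counting$times)
  dA <- array(0, c(K, K, m))
  j <- counting$jumps
  if (nrow(j) > 0L) {
    lin <- (j$from + 1L) + K * j$to + K * K * (j$k - 1L)
    agg <- rowsum(1 / j$Yfrom, lin)
    dA[as.integer(rownames(agg))] <- agg
  }
  if (m > 0L) {
    rs <- apply(dA, c(1, 3), sum)   # K x m row sums
    for (g in seq_len(K)) dA[g, g, ] <- -rs[g, ]
  }
  A <- dA
  if (m > 1L) A <- aperm(apply(dA, c(1, 2), cumsum), c(2, 3, 1))
  structure(list(model = counting$model, n = counting$n,
                 times = counting$times, dA = dA, A = A),
            class = "msm_cumhaz")
}

#' Aalen-Johansen estimator of the transition probability matrix
#'
#' Product integral of `I + dA` over the event times, yielding the matrix of
#' estimated transition probabilities `P(0, t)`.  Rows sum to one and all
#' entries lie in `[0, 1]` whenever every off-diagonal increment of the
#' input is at most one (which holds for any valid counting system, since
#' `dN_gh(t) <= Y_g(t-)`).  As an estimator of state occupation
#' probabilities it is consistent even in non-Markov models under random
#' censoring.
#'
#' @param cumhaz An [nelson_aalen()] object (or any `msm_cumhaz` whose rows
#'   sum to zero, e.g. a multiplier process).
#' @return An object of class `msm_probmat`: list with `times` and the array
#'   `P` (`K x K x m`) of `P(0, times[k])`.
#' @export
aalen_johansen <- function(cumhaz) {
  stopifnot(inherits(cumhaz, "msm_cumhaz"))
  K <- dim(cumhaz$dA)[1L]
  off <- cumhaz$dA
  for (g in seq_len(K)) off[g, g, ] <- 0
  if (any(off > 1 + 1e-12))
    stop("an off-diagonal increment exceeds 1; invalid counting input")
  P <- prodint_prefix_cpp(cumhaz$dA)
  structure(list(model = cumhaz$model, n = cumhaz$n,
                 times = cumhaz$times, P = P),
            class = "msm_probmat")
}

#' Evaluate an Aalen-Johansen probability matrix
#'
#' @param probs An [aalen_johansen()] object.
#' @param t A single evaluation time.
#' @return The `K x K` matrix `P(0, t)` (the identity for `t` before the
#'   first event).
#' @export
aje_matrix <- function(probs, t) {
  stopifnot(inherits(probs, "msm_probmat"))
  k <- findInterval(t, probs$times)
  if (k == 0L) diag(dim(probs$P)[1L]) else probs$P[, , k]
}

#' Kaplan-Meier component specifications
#'
#' The five composite-event Kaplan-Meier estimators of the progressive
#' six-state model.  Each is an ordinary Kaplan-Meier estimator over a
#' composite event process: component `j` has risk set `R_j` (states whose
#' occupants are at risk) and event set `E_j` (transitions counted as
#' events):
#'
#' * `j = 1`: onset of the first chronic GvHD episode, or death/relapse
#'   before it (`R = {0}`, events `0->1, 0->5`);
#' * `j = 2`: onset of the second episode, or death/relapse before it
#'   (`R = {0,1,2}`, events `2->3, 0->5, 1->5, 2->5`);
#' * `j = 3`: recovery from the first episode, or death/relapse before it
#'   (`R = {0,1}`, events `1->2, 0->5, 1->5`);
#' * `j = 4`: relapse-free survival: any death/relapse (`R = {0,...,4}`);
#' * `j = 5`: recovery from the second episode, or death/relapse before it
#'   (`R = {0,...,3}`, events `3->4, 0->5, 1->5, 2->5, 3->5`).
#'
#' Each component also admits a bilinear representation
#' `f_j(A)(t) = u_j(t)' A(t) v_j(t)` with `u_j` the at-risk weights
#' `Y_g(t-) / sum_{g' in R_j} Y_g'(t-)` over `R_j` and `v_j` the indicator
#' of the target states; the Kaplan-Meier component is the product integral
#' of that scalar cumulative hazard.  The target-state indicators are
#' exposed as `targets`.
#'
#' @param j Component index in `1:5`.
#' @return A list with fields `j`, `risk` (risk states), `events`
#'   (two-column matrix of event transitions) and `targets` (states whose
#'   entry constitutes an event).
#' @export
km_spec <- function(j) {
  stopifnot(j %in% 1:5)
  mk <- function(risk, ev, targets)
    list(j = j, risk = as.integer(risk),
         events = matrix(as.integer(ev), ncol = 2, byrow = TRUE,
                         dimnames = list(NULL, c("from", "to"))),
         targets = as.integer(targets))
  switch(j,
    mk(0, c(0, 1, 0, 5), c(1, 5)),
    mk(0:2, c(2, 3, 0, 5, 1, 5, 2, 5), c(3, 5)),
    mk(0:1, c(1, 2, 0, 5, 1, 5), c(2, 5)),
    mk(0:4, c(0, 5, 1, 5, 2, 5, 3, 5, 4, 5), 5),
    mk(0:3, c(3, 4, 0, 5, 1, 5, 2, 5, 3, 5), c(4, 5))
  )
}

#' Composite-event Kaplan-Meier component
#'
#' Standard Kaplan-Meier estimator over the composite event process of a
#' component specification: at each event time with `d` composite events and
#' `Y_R = sum_{g in R} Y_g(t-)` individuals at risk the survival curve is
#' multiplied by `1 - d / Y_R` (no update when `Y_R = 0`).  Individuals
#' leaving the risk set other than by a component event (censoring) are
#' removed without an event.
#'
#' @param counting A [build_counting()] object under the progressive
#'   six-state model.
#' @param spec A [km_spec()] component specification.
#' @return A [step_function()] on the counting grid.
#' @export
km_component <- function(counting, spec) {
  stopifnot(inherits(counting, "msm_counting"))
  m <- length(counting$times)
  if (m == 0L) return(step_function(numeric(), numeric(), 1))
  j <- counting$jumps
  K <- counting$model$K
  evkey <- spec$events[, 1] * K + spec$events[, 2]
  isev <- (j$from * K + j$to) %in% evkey
  d <- numeric(m)
  if (any(isev)) {
    agg <- rowsum(rep(1, sum(isev)), j$k[isev])
    d[as.integer(rownames(agg))] <- agg
  }
  Yrisk <- rowSums(counting$Y[, spec$risk + 1L, drop = FALSE])
  fac <- ifelse(Yrisk > 0, 1 - d / Yrisk, 1)
  step_function(counting$times, cumprod(fac), 1)
}

#' Chronic GvHD- and relapse-free survival, Kaplan-Meier combination
#'
#' The linear combination `S1 + S2 - S3 + S4 - S5` of the five composite
#' Kaplan-Meier components of [km_spec()], estimating the probability of
#' being alive, in remission and currently free of chronic GvHD under the
#' progressive six-state model without a Markov assumption.  The combination
#' is not constrained to `[0, 1]`: it can exceed one or drop below zero
#' (e.g. on [toy_table1()] it equals 7/6 at day 3 and -1/2 from day 6 on).
#' The unclipped curve is returned by default; set `clip = TRUE` for the
#' standard workaround that truncates to the unit interval.
#'
#' @param dataset An [msm_dataset()] under the progressive six-state model
#'   (or an already built [build_counting()] object).
#' @param clip Clip the returned curve to `[0, 1]`?
#' @return A [step_function()]; the five components are attached as
#'   attribute `"components"` (a list of step functions).
#' @examples
#' f <- cgrfs_km(toy_table1())
#' eval_stepfn(f, c(3, 6))   # 7/6, -1/2
#' @export
cgrfs_km <- function(dataset, clip = FALSE) {
  counting <- if (inherits(dataset, "msm_counting")) dataset
              else build_counting(dataset)
  if (counting$model$name != "prog6")
    stop("the Kaplan-Meier combination requires the progressive six-state model")
  comps <- lapply(1:5, function(j) km_component(counting, km_spec(j)))
  sgn <- c(1, 1, -1, 1, -1)
  vals <- numeric(length(counting$times))
  for (j in 1:5) vals <- vals + sgn[j] * comps[[j]]$values
  out <- step_function(counting$times, vals, 1)
  if (clip) out <- clip_unit(out)
  attr(out, "components") <- comps
  out
}

#' Chronic GvHD- and relapse-free survival, Aalen-Johansen estimator
#'
#' Under the progressive six-state model the endpoint is the sum of the
#' state occupation probabilities of states 0, 2 and 4, estimated by the
#' row-0 entries `P00 + P02 + P04` of the Aalen-Johansen matrix; under the
#' illness-death model with recovery it is the single occupation
#' probability `P00`.  Values always lie in `[0, 1]`.
#'
#' @param dataset An [msm_dataset()] under either supported model
#'   (or a [build_counting()] object).
#' @return A [step_function()].
#' @examples
#' eval_stepfn(cgrfs_aje(toy_table1()), 3)                     # 1
#' eval_stepfn(cgrfs_aje(map_prog6_to_idm3(toy_table1())), 3)  # 1
#' @export
cgrfs_aje <- function(dataset) {
  counting <- if (inherits(dataset, "msm_counting")) dataset
              else build_counting(dataset)
  states <- cgrfs_states(counting$model)
  na <- nelson_aalen(counting)
  if (length(counting$times) == 0L)
    return(step_function(numeric(), numeric(), 1))
  row0 <- prodint_row_cpp(na$dA, 0L)   # m x K, e_0' P(0, t_k)
  step_function(counting$times,
                rowSums(row0[, states + 1L, drop = FALSE]), 1)
}

# target state set of the CGRFS functional under each model
cgrfs_states <- function(model) {
  switch(model$name,
    prog6 = c(0L, 2L, 4L),
    idm3 = 0L,
    stop("unsupported model: ", model$name))
}
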