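#' Right-continuous step functions
#'
#' Light-weight carrier for all estimated curves: a right-continuous step
#' function with value `v0` on `[0, times[1])` and value `values[k]` on
#' `[times[k], times[k+1])`.
#'
#' @param times Sorted, strictly increasing positive jump times.
#' @param values Function values right after each jump.
#' @param v0 Value on `[0, times[1])`.
#' @return An object of class `stepfn`.
#' @export
step_function <- function(times, values, v0 = 1) {
  stopifnot(length(times) == length(values), !is.unsorted(times))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 v0 = as.numeric(v0)), class = "stepfn")
}

#' Evaluate a step function
#'
#' @param f A [step_function()].
#' @param t Evaluation times (vector).
#' @param left If `TRUE`, return the left limit `f(t-)` instead of `f(t)`.
#' @return Numeric vector of the same length as `t`.
#' @export
eval_stepfn <- function(f, t, left = FALSE) {
  idx <- findInterval(t, f$times, left.open = left)
  c(f$v0, f$values)[idx + 1L]
}

#' @export
print.stepfn <- function(x, ...) {
  cat(sprintf("<stepfn>: %d jumps, f(0)=%g", length(x$times), x$v0))
  if (length(x$times))
    cat(sprintf(", last jump at t=%g (value %g)",
                x$times[length(x$times)], x$values[length(x$values)]))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.stepfn <- function(x, ...) {
  data.frame(time = x$times, estimate = x$values)
}

#' Clip a curve to the unit interval
#'
#' Pointwise `max(0, min(1, f))`.  Used as the standard workaround when the
#' Kaplan-Meier linear combination estimates a probability outside `[0, 1]`;
#' idempotent and the identity on curves already inside the unit interval.
#'
#' @param f A [step_function()].
#' @return A clipped [step_function()] on the same grid.
#' @export
clip_unit <- function(f) {
  stopifnot(inherits(f, "stepfn"))
  step_function(f$times, pmin(1, pmax(0, f$values)), pmin(1, pmax(0, f$v0)))
}
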