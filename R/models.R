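#' Multistate model specifications
#'
#' A model specification fixes the finite state space `0, ..., K-1`, the set
#' of allowed direct transitions, and the absorbing states.  Two models are
#' built in:
#'
#' * `model_prog6()`: the progressive six-state model.  State 0 is
#'   "alive, no chronic GvHD yet", states 1 and 3 are the first and second
#'   episode of chronic GvHD, states 2 and 4 are "recovered" from the first
#'   and second episode, and state 5 ("death or relapse") is absorbing.
#'   The chain is strictly progressive: 0->1->2->3->4 with a death/relapse
#'   hazard out of every transient state.
#' * `model_idm3()`: the illness-death model with recovery.  State 0 is
#'   "alive and free of chronic GvHD", state 1 "alive with chronic GvHD"
#'   (with back transitions 1->0 allowed, so GvHD is recurrent without an
#'   episode limit), state 2 ("death or relapse") is absorbing.
#'
#' All individuals start in state 0.
#'
#' @param name Model label, `"prog6"` or `"idm3"`.
#' @return An object of class `msm_model` with fields `name`, `K`,
#'   `transitions` (two-column integer matrix of allowed from/to pairs),
#'   `absorbing` and `initial`.
#' @examples
#' model_prog6()
#' model_idm3()
#' @export
msm_model <- function(name = c("prog6", "idm3")) {
  name <- match.arg(name)
  if (name == "prog6") {
    trans <- rbind(
      c(0L, 1L), c(1L, 2L), c(2L, 3L), c(3L, 4L),
      c(0L, 5L), c(1L, 5L), c(2L, 5L), c(3L, 5L), c(4L, 5L)
    )
    K <- 6L
    absorbing <- 5L
  } else {
    trans <- rbind(c(0L, 1L), c(1L, 0L), c(0L, 2L), c(1L, 2L))
    K <- 3L
    absorbing <- 2L
  }
  colnames(trans) <- c("from", "to")
  structure(
    list(name = name, K = K, transitions = trans,
         absorbing = absorbing, initial = 0L),
    class = "msm_model"
  )
}

#' @rdname msm_model
#' @export
model_prog6 <- function() msm_model("prog6")

#' @rdname msm_model
#' @export
model_idm3 <- function() msm_model("idm3")

#' @export
print.msm_model <- function(x, ...) {
  cat(sprintf("<msm_model '%s'>: %d states, absorbing {%s}\n",
              x$name, x$K, paste(x$absorbing, collapse = ",")))
  cat("  transitions:",
      paste(sprintf("%d->%d", x$transitions[, 1], x$transitions[, 2]),
            collapse = ", "), "\n")
  invisible(x)
}

# is (from, to) an allowed transition of the model?
transition_allowed <- function(model, from, to) {
  key <- paste(model$transitions[, 1], model$transitions[, 2])
  paste(from, to) %in% key
}
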