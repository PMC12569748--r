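#' Multistate event-history datasets
#'
#' A dataset holds the observed transition paths of `n` individuals in one of
#' the supported multistate models, in long format: one row per observed
#' direct transition, plus (at most) one final censoring row per individual.
#' Censoring is coded as `NA` in the `to` column; on disk the token `cens`
#' is used, as in the usual long-format event tables.
#'
#' Within an individual the records must form a connected path: times are
#' strictly increasing, each record starts in the state the previous record
#' ended in, the first record starts in state 0, nothing follows entry into
#' an absorbing state, and the path terminates either by absorption or by a
#' single final censoring record.
#'
#' @param events A data.frame with columns `id`, `from`, `to`, `time`.
#'   `to` is an integer state or `NA` for censoring; `time` is a strictly
#'   positive event time (days).
#' @param model An [msm_model()].
#' @return An object of class `msm_dataset`: a list with fields `model`,
#'   `events` (records sorted by individual and time) and `n`.
#' @seealso [read_events()], [toy_table1()], [map_prog6_to_idm3()]
#' @export
msm_dataset <- function(events, model) {
  stopifnot(inherits(model, "msm_model"))
  events <- as.data.frame(events)
  need <- c("id", "from", "to", "time")
  if (!all(need %in% names(events)))
    stop("events must have columns id, from, to, time")
  events <- events[need]
  events$id <- as.character(events$id)
  events$from <- as.integer(events$from)
  events$to <- as.integer(events$to)
  events$time <- as.numeric(events$time)
  # deterministic storage order: individuals in order of first appearance
  ord <- order(match(events$id, unique(events$id)), events$time)
  events <- events[ord, , drop = FALSE]
  rownames(events) <- NULL
  x <- structure(
    list(model = model, events = events, n = length(unique(events$id))),
    class = "msm_dataset"
  )
  validate_msm_dataset(x)
  x
}

validate_msm_dataset <- function(x) {
  ev <- x$events
  model <- x$model
  if (nrow(ev) == 0L) return(invisible(x))
  if (anyNA(ev$from) || anyNA(ev$time))
    stop("missing values in 'from' or 'time'")
  if (any(ev$time <= 0))
    stop("event times must be strictly positive")
  states <- 0:(model$K - 1L)
  if (!all(ev$from %in% states))
    stop("'from' contains states outside the model's state space")
  obs <- !is.na(ev$to)
  if (!all(ev$to[obs] %in% states))
    stop("'to' contains states outside the model's state space")
  if (any(ev$from[obs] == ev$to[obs]))
    stop("self-loop transitions are not allowed")
  bad <- obs & !transition_allowed(model, ev$from, ev$to)
  if (any(bad)) {
    b <- which(bad)[1L]
    stop(sprintf("transition %d->%d (id %s, t=%g) is not allowed under model '%s'",
                 ev$from[b], ev$to[b], ev$id[b], ev$time[b], model$name))
  }
  for (rows in split(seq_len(nrow(ev)), ev$id)) {
    e <- ev[rows, , drop = FALSE]
    id <- e$id[1L]
    if (any(diff(e$time) <= 0))
      stop(sprintf("times not strictly increasing for id %s", id))
    if (e$from[1L] != model$initial)
      stop(sprintf("first record of id %s does not start in state %d",
                   id, model$initial))
    k <- nrow(e)
    if (k > 1L && any(e$from[-1L] != e$to[-k]))
      stop(sprintf("path of id %s is not connected (from != previous to)", id))
    cens <- is.na(e$to)
    if (sum(cens) > 1L || (any(cens) && !cens[k]))
      stop(sprintf("id %s: at most one censoring record is allowed and it must be last", id))
    absorbed <- !cens & e$to %in% model$absorbing
    if (any(absorbed) && which(absorbed)[1L] < k)
      stop(sprintf("id %s has records after entering an absorbing state", id))
    if (!cens[k] && !absorbed[k])
      stop(sprintf("id %s: path must end by censoring or absorption", id))
  }
  invisible(x)
}

#' @export
print.msm_dataset <- function(x, ...) {
  ntrans <- sum(!is.na(x$events$to))
  ncens <- sum(is.na(x$events$to))
  cat(sprintf("<msm_dataset '%s'>: %d individuals, %d transitions, %d censorings\n",
              x$model$name, x$n, ntrans, ncens))
  invisible(x)
}

#' Read and write long-format event tables
#'
#' The on-disk format is a comma-separated file with header
#' `id,from,to,time`, one record per row; censoring is marked by the token
#' `cens` in the `to` column (accepted case-insensitively, with or without
#' plain or typographic quotes).
#'
#' @param path Path of the CSV file.
#' @param model An [msm_model()] the records are validated against.
#' @return `read_events()` returns a validated [msm_dataset()];
#'   `write_events()` returns `path` invisibly.  A written file read back
#'   reproduces the dataset exactly.
#' @export
read_events <- function(path, model) {
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  names(raw) <- tolower(names(raw))
  need <- c("id", "from", "to", "time")
  if (!all(need %in% names(raw)))
    stop("expected CSV header id,from,to,time")
  if (nrow(raw) == 0L)
    return(msm_dataset(data.frame(id = character(), from = integer(),
                                  to = integer(), time = numeric()), model))
  to <- gsub("[\"“”‘’']", "", raw$to)
  is_cens <- tolower(to) == "cens"
  to_int <- rep(NA_integer_, length(to))
  to_int[!is_cens] <- suppressWarnings(as.integer(to[!is_cens]))
  if (anyNA(to_int[!is_cens]))
    stop("malformed 'to' entries (neither a state nor the censoring token)")
  from <- suppressWarnings(as.integer(raw$from))
  time <- suppressWarnings(as.numeric(raw$time))
  if (anyNA(from) || anyNA(time))
    stop("malformed 'from' or 'time' entries")
  msm_dataset(data.frame(id = raw$id, from = from, to = to_int, time = time),
              model)
}

#' @param dataset An [msm_dataset()].
#' @rdname read_events
#' @export
write_events <- function(dataset, path) {
  stopifnot(inherits(dataset, "msm_dataset"))
  ev <- dataset$events
  out <- data.frame(id = ev$id, from = ev$from,
                    to = ifelse(is.na(ev$to), "cens", as.character(ev$to)),
                    time = ev$time)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Three-individual example dataset
#'
#' The small worked example used throughout: individual 1 is censored in
#' state 0 at day 2; individual 2 runs through both chronic GvHD episodes
#' (onset at day 1, recovery at day 3, second onset at day 6) and dies at
#' day 7; individual 3 has a first chronic GvHD onset at day 4 and is
#' censored at day 5.  On these data the Kaplan-Meier combination exceeds 1
#' at day 3 and is negative from day 6 on.
#'
#' @return An [msm_dataset()] under the progressive six-state model.
#' @examples
#' toy <- toy_table1()
#' cgrfs_km(toy)
#' @export
toy_table1 <- function() {
  msm_dataset(
    data.frame(
      id = c(1L, 2L, 2L, 2L, 2L, 3L, 3L),
      from = c(0L, 0L, 1L, 2L, 3L, 0L, 1L),
      to = c(NA, 1L, 2L, 3L, 5L, 1L, NA),
      time = c(2, 1, 3, 6, 7, 4, 5)
    ),
    model_prog6()
  )
}

#' Collapse the progressive six-state model to the illness-death model
#'
#' Maps every path of a progressive six-state dataset into the illness-death
#' model with recovery: states 0, 2, 4 (alive without current chronic GvHD)
#' map to state 0, states 1 and 3 (alive with chronic GvHD) map to state 1,
#' and state 5 (death/relapse) maps to state 2.  Event times, censoring
#' times and absorption times are preserved exactly; a second episode
#' becomes a recurrence of the 0->1 transition.
#'
#' @param dataset An [msm_dataset()] under the progressive six-state model.
#' @return An [msm_dataset()] under the illness-death model with recovery.
#' @export
map_prog6_to_idm3 <- function(dataset) {
  stopifnot(inherits(dataset, "msm_dataset"))
  if (dataset$model$name != "prog6")
    stop("input dataset must be under the progressive six-state model")
  statemap <- c(0L, 1L, 0L, 1L, 0L, 2L)
  ev <- dataset$events
  ev$from <- statemap[ev$from + 1L]
  ev$to <- ifelse(is.na(ev$to), NA_integer_, statemap[ev$to + 1L])
  msm_dataset(ev, model_idm3())
}

#' Counting processes and at-risk sets
#'
#' Builds the transition-specific counting processes `N_gh` and the at-risk
#' processes `Y_g` of a dataset on the grid of observed transition times.
#' `Y_g(t-)` counts the individuals occupying state `g` just before `t` and
#' still uncensored at `t`; an individual leaving `g` at `t` (by transition
#' or by censoring) is therefore still at risk at `t-`.  The individual jump
#' registry is retained because the wild bootstrap draws one multiplier per
#' individual jump.
#'
#' @param dataset An [msm_dataset()].
#' @return An object of class `msm_counting`: a list with fields
#'   \describe{
#'     \item{model, n}{the model and the number of individuals;}
#'     \item{times}{sorted distinct observed transition times (the event grid);}
#'     \item{Y}{an `m x K` matrix, `Y[k, g+1] = Y_g(times[k]-)`;}
#'     \item{jumps}{one row per individual observed transition: `id`, `from`,
#'       `to`, `time`, grid index `k`, and `Y_from(time-)` as `Yfrom`.}
#'   }
#' @examples
#' cnt <- build_counting(toy_table1())
#' cnt$times
#' cnt$Y
#' @export
build_counting <- function(dataset) {
  stopifnot(inherits(dataset, "msm_dataset"))
  ev <- dataset$events
  model <- dataset$model
  K <- model$K
  n <- dataset$n
  if (nrow(ev) == 0L) {
    return(structure(
      list(model = model, n = 0L, times = numeric(),
           Y = matrix(0, 0, K),
           jumps = data.frame(id = character(), from = integer(),
                              to = integer(), time = numeric(),
                              k = integer(), Yfrom = numeric())),
      class = "msm_counting"))
  }
  # occupancy intervals: record r means state ev$from[r] on (start, time],
  # where start is the previous record time of the same individual (0 first)
  first <- !duplicated(ev$id)
  start <- c(0, ev$time[-nrow(ev)])
  start[first] <- 0
  obs <- !is.na(ev$to)
  grid <- sort(unique(ev$time[obs]))
  m <- length(grid)
  Y <- matrix(0, m, K)
  for (g in 0:(K - 1L)) {
    sel <- ev$from == g
    if (!any(sel)) next
    Y[, g + 1L] <- findInterval(grid, sort(start[sel]), left.open = TRUE) -
      findInterval(grid, sort(ev$time[sel]), left.open = TRUE)
  }
  jumps <- data.frame(id = ev$id[obs], from = ev$from[obs], to = ev$to[obs],
                      time = ev$time[obs])
  jumps <- jumps[order(jumps$time, match(jumps$id, unique(ev$id))), ,
                 drop = FALSE]
  rownames(jumps) <- NULL
  jumps$k <- match(jumps$time, grid)
  jumps$Yfrom <- Y[cbind(jumps$k, jumps$from + 1L)]
  structure(
    list(model = model, n = n, times = grid, Y = Y, jumps = jumps),
    class = "msm_counting"
  )
}

#' @export
print.msm_counting <- function(x, ...) {
  cat(sprintf("<msm_counting '%s'>: n=%d, %d event times, %d individual jumps\n",
              x$model$name, x$n, length(x$times), nrow(x$jumps)))
  invisible(x)
}
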