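# Export of estimates and interval results: CSV plus a JSON sidecar that
# records everything needed to regenerate the artifact (estimator, model,
# n, B, seed, ...).

#' Write an estimated curve or interval result with a JSON sidecar
#'
#' `write_estimate()` writes a [step_function()] as a two-column CSV
#' (`time,estimate`, one row per jump time); `write_interval()` writes a
#' CI/band data.frame as returned by [loglog_ci()] or [loglog_band()].
#' Both write a `<path>.json` sidecar with the supplied metadata, so that
#' the artifact can be regenerated from the sidecar alone.
#'
#' @param f A [step_function()].
#' @param path Output CSV path.
#' @param meta Named list of metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_estimate <- function(f, path, meta = list()) {
  stopifnot(inherits(f, "stepfn"))
  utils::write.csv(as.data.frame(f), path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @param x A data.frame with columns `time`, `estimate`, `lower`, `upper`.
#' @rdname write_estimate
#' @export
write_interval <- function(x, path, meta = list()) {
  stopifnot(is.data.frame(x))
  utils::write.csv(x, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
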