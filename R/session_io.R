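# On-disk session container. One file per session, written with R's native
# serialization plus an explicit schema version so format drift fails loudly
# rather than silently. Integer data round-trip bit-exactly; doubles are
# serialized at full precision (round-trip is exact, well inside the 1e-12
# relative guarantee).

SESSION_SCHEMA <- "lfpdyn-session-v1"

#' Write a session bundle to disk
#'
#' Validates the bundle, then serializes it together with a schema version
#' tag. `read_session(write_session(b, path))` reproduces `b` exactly.
#'
#' @param bundle A [session_bundle()].
#' @param path Output file path (conventionally `*.rds`).
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(bundle, path) {
  validate_session_bundle(bundle)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("write_session: directory does not exist: ", dir)
  }
  saveRDS(list(schema = SESSION_SCHEMA, bundle = bundle), path)
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Inverse of [write_session()]. The stored schema version must match the
#' version this package writes; the bundle is re-validated on load so a
#' corrupted or hand-edited file fails with a named error.
#'
#' @param path File written by [write_session()].
#' @return A validated [session_bundle()].
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("read_session: no such file: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("read_session: I/O error reading ",
                                           path, ": ", conditionMessage(e)))
  if (!is.list(obj) || is.null(obj$schema)) {
    stop("read_session: not a session container (missing schema tag): ", path)
  }
  if (!identical(obj$schema, SESSION_SCHEMA)) {
    stop("read_session: schema version mismatch: file has '", obj$schema,
         "', this package reads '", SESSION_SCHEMA, "'")
  }
  if (is.null(obj$bundle) || !inherits(obj$bundle, "session_bundle")) {
    stop("read_session: container is missing the session bundle group")
  }
  validate_session_bundle(obj$bundle)
  obj$bundle
}

#' Export a trial table to CSV
#'
#' @param trials A [trial_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  validate_trial_table(trials)
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}
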