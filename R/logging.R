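# Structured experiment log: append-only records, optionally mirrored to a
# JSONL file (one JSON object per line), plus a pluggable notifier for
# records that warrant operator attention.

#' Experiment logger
#'
#' Append-only structured log shared by all modules of an experiment. Each
#' record carries a timestamp, the frame index, the emitting module, a
#' severity, a message and a structured payload. Records can be mirrored to
#' a JSONL file and forwarded to a notifier (see [fileNotifier()]).
#'
#' @slot env environment holding the records and sinks.
#' @export
setClass("ExperimentLogger", representation(env = "environment"))

#' @param jsonlPath optional path of a JSONL file to append records to.
#' @param notifier optional function(record) called for records with severity
#'   `"warning"` or `"error"`.
#' @rdname ExperimentLogger-class
#' @export
ExperimentLogger <- function(jsonlPath = NULL, notifier = NULL) {
  env <- new.env(parent = emptyenv())
  env$records <- vector("list", 256L)
  env$n <- 0L
  env$jsonlPath <- jsonlPath
  env$notifier <- notifier
  new("ExperimentLogger", env = env)
}

#' Append a record to an experiment log
#'
#' @param logger an [ExperimentLogger-class].
#' @param module emitting module name.
#' @param message human-readable message.
#' @param frame frame index the record refers to.
#' @param severity one of `"info"`, `"warning"`, `"error"`.
#' @param payload named list of structured values.
#' @return the record, invisibly.
#' @export
logRecord <- function(logger, module, message, frame = NA_integer_,
                      severity = "info", payload = list()) {
  stopifnot(severity %in% c("info", "warning", "error"))
  rec <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
              frame_index = frame, module = module, severity = severity,
              message = message, payload = payload)
  e <- logger@env
  e$n <- e$n + 1L
  if (e$n > length(e$records))
    e$records <- c(e$records, vector("list", length(e$records)))
  e$records[[e$n]] <- rec
  if (!is.null(e$jsonlPath))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), "\n",
        sep = "", file = e$jsonlPath, append = TRUE)
  if (!is.null(e$notifier) && severity %in% c("warning", "error"))
    e$notifier(rec)
  invisible(rec)
}

#' Retrieve log records
#'
#' @param logger an [ExperimentLogger-class].
#' @param module optional module filter.
#' @param severity optional severity filter.
#' @return list of records, in append order.
#' @export
logRecords <- function(logger, module = NULL, severity = NULL) {
  recs <- logger@env$records[seq_len(logger@env$n)]
  if (!is.null(module))
    recs <- Filter(function(r) r$module == module, recs)
  if (!is.null(severity))
    recs <- Filter(function(r) r$severity == severity, recs)
  recs
}

setMethod("show", "ExperimentLogger", function(object) {
  sev <- vapply(logRecords(object), `[[`, "", "severity")
  cat("ExperimentLogger:", length(sev), "records (",
      sum(sev == "warning"), "warnings,", sum(sev == "error"), "errors )\n")
})

#' File-append notifier backend
#'
#' Minimal notifier: appends each forwarded record as a JSON line to a file.
#' Stands in for chat/webhook integrations; any `function(record)` with the
#' same signature can be plugged into [ExperimentLogger()].
#'
#' @param path file to append to.
#' @return a notifier function.
#' @export
fileNotifier <- function(path) {
  function(record) {
    cat(jsonlite::toJSON(record, auto_unbox = TRUE, null = "null"), "\n",
        sep = "", file = path, append = TRUE)
  }
}
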