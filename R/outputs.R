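# Output writers: tracks CSV (diffable, 6 significant digits), ground-truth
# CSV, events JSONL, summary JSON with the resolved config embedded, and
# 16-bit single-plane TIFF images named frame{k}_pos{p}_{channel}.tiff.

# internal: format numerics at 6 significant digits for byte-stable CSVs
formatTable <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- formatC(df[[nm]], digits = 6, format = "g")
  df
}

#' Write the standard output set of a run
#'
#' @param dir output directory (created if needed; must be writable).
#' @param trackTable per-frame track table (may have zero rows).
#' @param config the resolved [ExperimentConfig-class].
#' @param summary named list of run metrics.
#' @param logger optional [ExperimentLogger-class] dumped to `events.jsonl`.
#' @param truth optional ground-truth table for `truth.csv`.
#' @return the directory, invisibly.
#' @export
writeOutputs <- function(dir, trackTable, config, summary = list(),
                         logger = NULL, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  if (is.null(trackTable) || nrow(trackTable) == 0L)
    trackTable <- data.frame(frame = integer(), position = character(),
                             track_id = integer(), cx = numeric(),
                             cy = numeric(), area = numeric())
  utils::write.csv(formatTable(trackTable),
                   file.path(dir, "tracks.csv"), row.names = FALSE)
  if (!is.null(truth))
    utils::write.csv(formatTable(truth), file.path(dir, "truth.csv"),
                     row.names = FALSE)
  if (!is.null(logger)) {
    con <- file(file.path(dir, "events.jsonl"), "w")
    for (rec in logRecords(logger))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
    close(con)
  }
  out <- list(config = config@values, metrics = summary)
  jsonlite::write_json(out, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write one camera frame as a 16-bit TIFF
#'
#' @param dir output directory.
#' @param img numeric image matrix (intensity units; clamped to 0..65535).
#' @param frame,position,channel filename components.
#' @return the file path, invisibly.
#' @export
writeFrameTiff <- function(dir, img, frame, position, channel) {
  path <- file.path(dir, sprintf("frame%d_pos%s_%s.tiff", frame, position,
                                 channel))
  scaled <- pmin(pmax(img, 0), 65535) / 65535
  tiff::writeTIFF(scaled, path, bits.per.sample = 16)
  invisible(path)
}
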