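## Chronological session logging and tabular exports.

#' Create a session event
#'
#' One record of atlas activity: which gene(s) were visualized or compared,
#' in which view mode, on which model, and when. Timestamps are UTC ISO-8601
#' with millisecond precision.
#'
#' @param action One of `"select_gene"`, `"compare_side_by_side"`,
#'   `"heatmap"`, `"group_contrast"`, `"snapshot"`, `"export"`.
#' @param genes Character vector of gene IDs involved (joined with `;` in
#'   the log; may be empty for non-gene actions).
#' @param mode View mode in effect (`"normalized"` or `"absolute"`).
#' @param modelId Identifier of the model acted on.
#' @param timestamp POSIXct or ISO-8601 string; defaults to the current UTC
#'   time.
#' @return One-row data.frame usable with [logEvent()].
#' @export
sessionEvent <- function(action, genes = character(), mode = "normalized",
                         modelId = "model1", timestamp = Sys.time()) {
  if (!action %in% .sessionActions)
    .segStop("badAction",
             sprintf("unknown action '%s'; must be one of: %s", action,
                     paste(.sessionActions, collapse = ", ")))
  mode <- viewMode(mode)
  ts <- if (inherits(timestamp, "POSIXt"))
    format(timestamp, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  else as.character(timestamp)
  if (!grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}", ts))
    .segStop("badTimestamp", sprintf("timestamp '%s' is not ISO-8601", ts))
  data.frame(timestamp = ts, action = action,
             genes = paste(genes, collapse = ";"),
             view_mode = mode, model_id = modelId, stringsAsFactors = FALSE)
}

#' Append an event to a session log
#'
#' The log is append-only and chronological: the new event's timestamp must
#' not precede the last logged one.
#'
#' @param log A [SessionLog].
#' @param event A one-row event from [sessionEvent()].
#' @return The extended [SessionLog].
#' @export
logEvent <- function(log, event) {
  stopifnot(is(log, "SessionLog"))
  if (!is.data.frame(event) || nrow(event) != 1L ||
      !identical(colnames(event), .sessionCols))
    .segStop("badArgument", "'event' must be a one-row sessionEvent()")
  ev <- log@events
  if (nrow(ev) && event$timestamp < ev$timestamp[nrow(ev)])
    .segStop("nonMonotoneTimestamp",
             sprintf("event timestamp %s precedes last logged %s",
                     event$timestamp, ev$timestamp[nrow(ev)]))
  new("SessionLog", events = rbind(ev, event))
}

#' Write a session log to a TSV backup file
#'
#' One row per event, columns `timestamp`, `action`, `genes`, `view_mode`,
#' `model_id`; multiple genes of a comparison are joined with `;`. The file
#' is valid TSV after every write, so it can serve as a crash-safe running
#' backup of a session.
#'
#' @param log A [SessionLog].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeSessionLog <- function(log, path) {
  stopifnot(is(log, "SessionLog"))
  ok <- tryCatch({
    utils::write.table(log@events, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    .segStop("ioFailure", sprintf("cannot write session log to '%s'", path),
             category = "io")
  invisible(path)
}

#' Read a session log back from its TSV backup file
#' @param path Path written by [writeSessionLog()].
#' @return A [SessionLog].
#' @export
readSessionLog <- function(path) {
  if (!file.exists(path))
    .segStop("fileNotFound", sprintf("file not found: %s", path), category = "io")
  ev <- utils::read.delim(path, colClasses = "character")
  if (!identical(colnames(ev), .sessionCols))
    .segStop("badArgument", sprintf("'%s' is not a session log", path))
  new("SessionLog", events = ev)
}

#' @describeIn exportTable Ranked similarity table: columns `rank`, `gene`,
#'   `similarity_percent` (two decimals).
#' @export
setMethod("exportTable", "SimilarityTable", function(x, path, delim = "\t") {
  df <- similarityRecords(x)
  if (nrow(df) == 0L)
    .segStop("emptyTable", "similarity table has no records to export")
  df$similarity_percent <- sprintf("%.2f", df$similarity_percent)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
})

#' @describeIn exportTable Heatmap result: columns `segment`, `diff`,
#'   `hex_color`.
#' @export
setMethod("exportTable", "HeatmapResult", function(x, path, delim = "\t") {
  if (length(x@diffs) == 0L)
    .segStop("emptyTable", "heatmap result has no segments to export")
  df <- data.frame(segment = x@segmentIds,
                   diff = sprintf("%.6g", x@diffs),
                   hex_color = unname(segmentHexColors(x@colors)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
})
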