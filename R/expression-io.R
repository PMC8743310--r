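## Expression matrix CSV I/O.
## Dialect: UTF-8, comma-separated, header `gene,<seg1>,...,<segN>`; one row
## per gene; all cells numeric; values written with 6 significant digits.

.parseExpressionCSV <- function(path, what = "expression") {
  if (!file.exists(path))
    .segStop("fileNotFound", sprintf("file not found: %s", path), category = "io")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    .segStop("missingHeader", sprintf("%s file '%s' is empty", what, path))
  header <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  header <- trimws(header)
  if (length(header) < 2L || tolower(header[1L]) != "gene")
    .segStop("missingHeader",
             sprintf("first header cell must be 'gene', got '%s'", header[1L]))
  segs <- header[-1L]
  if (anyDuplicated(segs))
    .segStop("duplicateSegmentID",
             sprintf("duplicate segment IDs in header: %s",
                     paste(unique(segs[duplicated(segs)]), collapse = ", ")))
  body <- lines[-1L]
  if (length(body) == 0L)
    .segStop("emptyMatrix", sprintf("%s file '%s' has no gene rows", what, path))
  cells <- strsplit(body, ",", fixed = TRUE)
  nfield <- lengths(cells)
  if (any(nfield != length(header)))
    .segStop("raggedRow",
             sprintf("row %d has %d fields, expected %d",
                     which(nfield != length(header))[1L] + 1L,
                     nfield[nfield != length(header)][1L], length(header)))
  genes <- trimws(vapply(cells, `[[`, character(1), 1L))
  if (anyDuplicated(genes))
    .segStop("duplicateGeneID",
             sprintf("duplicate gene IDs: %s",
                     paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  vals <- vapply(cells, function(x) suppressWarnings(as.numeric(x[-1L])),
                 numeric(length(segs)))
  vals <- if (length(segs) == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (any(is.na(vals))) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    .segStop("nonNumericCell",
             sprintf("non-numeric value for gene '%s', segment '%s'",
                     genes[bad[1L]], segs[bad[2L]]))
  }
  dimnames(vals) <- list(genes, segs)
  vals
}

#' Load a genes-by-segments expression matrix from CSV
#'
#' Reads a log2 CPM expression matrix in the atlas CSV dialect: a header row
#' `gene,<segment IDs...>` followed by one numeric row per gene. Segment IDs
#' take their canonical order from the header. If `expectedSegments` is given
#' (typically the number of pieces of the matched 3D model), the column count
#' must equal it — datasets must be compatible with the segmentation of the
#' model they are mapped onto.
#'
#' @param path Path to the CSV file.
#' @param expectedSegments Optional positive integer; required number of
#'   segment columns.
#' @return A [SegmentExperiment].
#' @seealso [writeExpressionMatrix()], [log2CPM()]
#' @export
loadExpressionMatrix <- function(path, expectedSegments = NULL) {
  vals <- .parseExpressionCSV(path, "expression")
  if (any(!is.finite(vals)))
    .segStop("nonFiniteValue", "expression values must be finite")
  if (!is.null(expectedSegments) && ncol(vals) != expectedSegments)
    .segStop("segmentCountMismatch",
             sprintf(paste0("dataset has %d segments but the model expects %d; ",
                            "dataset and 3D model are incompatible"),
                     ncol(vals), as.integer(expectedSegments)))
  SegmentExperiment(vals)
}

#' Load a raw count matrix from CSV
#'
#' Same dialect as [loadExpressionMatrix()], but values are raw per-segment
#' library counts (non-negative; every segment must have a positive total).
#'
#' @param path Path to the CSV file.
#' @return A [SegmentCounts].
#' @export
loadCountMatrix <- function(path) {
  vals <- .parseExpressionCSV(path, "count")
  SegmentCounts(vals)
}

#' Write an expression matrix to CSV
#'
#' Writes the atlas CSV dialect with values at 6 significant digits.
#' Writing then re-loading is idempotent: a second write/load cycle
#' reproduces gene IDs, segment IDs and values bit-identically.
#'
#' @param x A [SegmentExperiment], or a [SegmentCounts] (written with the
#'   same layout).
#' @param path Output file path.
#' @param digits Significant digits for values (default 6).
#' @return The path, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, digits = 6L) {
  m <- if (is(x, "SegmentExperiment")) exprValues(x)
       else if (is(x, "SegmentCounts")) assay(x, "counts")
       else .segStop("badArgument", "'x' must be a SegmentExperiment or SegmentCounts")
  fmt <- sprintf("%%.%dg", as.integer(digits))
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf(fmt, m[i, ])), collapse = ",")
  }, character(1))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste(c("gene", colnames(m)), collapse = ","), rows), con)
  invisible(path)
}
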