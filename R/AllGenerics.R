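#' @importFrom methods setGeneric setClass setMethod setValidity new validObject is slot
#' @importFrom stats cor rnorm
#' @importFrom utils read.delim write.table head
NULL

#' Segment identifiers of an object
#'
#' Every segatlas container (expression matrix, segmented mesh, color map, ...)
#' carries the ordered identifiers of the anatomical segments it covers; the
#' order is the canonical model order used for gradients and exploded layouts.
#'
#' @param x A segatlas object.
#' @return Character vector of segment IDs in canonical order.
#' @export
setGeneric("segmentIds", function(x) standardGeneric("segmentIds"))

#' Number of segments
#' @param x A segatlas object.
#' @return Integer scalar.
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' Export a result table to a delimited text file
#'
#' Serializes ranked similarity tables and per-segment heatmap results in the
#' tab-separated layout used by the atlas export functions (a `delim` of ","
#' switches to CSV).
#'
#' @param x A [SimilarityTable] or [HeatmapResult].
#' @param path Output file path.
#' @param delim Field delimiter, tab by default.
#' @return The path, invisibly.
#' @export
setGeneric("exportTable", function(x, path, delim = "\t") standardGeneric("exportTable"))
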