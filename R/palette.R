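## Expression-to-color mapping: linear gradient interpolation per segment.

#' Linearly interpolate a palette color
#'
#' Channelwise linear interpolation between a palette's low and high RGB
#' endpoints: `c = round(low + t * (high - low))`, rounding half away from
#' zero so the midpoint of the default palette is exactly (128, 0, 128).
#'
#' @param t Numeric vector of interpolation parameters in \[0, 1\] (0 = low
#'   expression, 1 = high).
#' @param palette A [Palette] (default: blue-to-red atlas palette).
#' @return Integer RGB triple if `t` is scalar; otherwise a `length(t)` x 3
#'   integer matrix.
#' @examples
#' interpolateColor(0)    # c(0, 0, 255)  blue
#' interpolateColor(1)    # c(255, 0, 0)  red
#' interpolateColor(0.5)  # c(128, 0, 128)
#' @export
interpolateColor <- function(t, palette = segPalette("default")) {
  stopifnot(is(palette, "Palette"))
  if (!is.numeric(t) || any(!is.finite(t)))
    .segStop("badArgument", "'t' must be finite numeric")
  if (any(t < 0) || any(t > 1))
    .segStop("outOfRange",
             sprintf("interpolation parameter out of [0, 1]: %g",
                     t[t < 0 | t > 1][1L]))
  low <- palette@low
  high <- palette@high
  m <- outer(t, as.numeric(high - low)) + rep(as.numeric(low), each = length(t))
  m <- matrix(as.integer(.roundHalfAway(m)), ncol = 3L)
  colnames(m) <- c("r", "g", "b")
  if (length(t) == 1L) m[1L, ] else m
}

#' Map one gene's expression onto per-segment colors
#'
#' Looks up the gene's per-segment log2 CPM values, scales them to \[0, 1\]
#' with [normalizeGene()] under the requested view mode, and interpolates each
#' through the palette. In normalized view the minimum-expression segment gets
#' exactly the low color and the maximum exactly the high color; a flat gene
#' colors all segments with the palette midpoint. In absolute view the scale
#' is the dataset-wide log2 CPM range of `x`.
#'
#' @param x A [SegmentExperiment].
#' @param gene Gene ID present in `x`.
#' @param mode `"normalized"` or `"absolute"`.
#' @param palette A [Palette].
#' @return A [SegmentColorMap] recording gene, mode and palette provenance.
#' @export
geneToSegmentColors <- function(x, gene, mode = c("normalized", "absolute"),
                                palette = segPalette("default")) {
  stopifnot(is(x, "SegmentExperiment"))
  mode <- viewMode(mode)
  .assertScalarString(gene, "gene")
  if (!gene %in% rownames(x))
    .segStop("unknownGene", sprintf("gene '%s' not in dataset", gene))
  v <- exprValues(x)[gene, ]
  rng <- if (mode == "absolute") range(exprValues(x)) else NULL
  t <- withCallingHandlers(
    normalizeGene(v, mode, datasetRange = rng),
    warning = function(w) invokeRestart("muffleWarning"))
  cols <- interpolateColor(as.numeric(t), palette)
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = 1L)
  new("SegmentColorMap", segmentIds = segmentIds(x), colors = cols,
      sourceGene = gene, mode = mode, palette = palette)
}

# internal: color map from an arbitrary per-segment unit-interval vector
.colorMapFromUnit <- function(t, segIds, source, mode, palette) {
  cols <- interpolateColor(as.numeric(t), palette)
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = 1L)
  new("SegmentColorMap", segmentIds = segIds, colors = cols,
      sourceGene = source, mode = mode, palette = palette)
}
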