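## Normalization: raw counts -> log2 CPM, and per-gene scaling for display.

#' Log2 counts-per-million transform
#'
#' Converts raw per-segment library counts to the log2 CPM scale used
#' throughout the atlas:
#' \deqn{v_{gs} = \log_2\!\left(\frac{c_{gs}}{\sum_g c_{gs}} \times 10^6 + p\right)}
#' where \eqn{p} is a prior pseudo-count (default 1, i.e. log2(CPM + 1), so a
#' zero count maps to 0). Columns are invariant under uniform scaling of a
#' library's counts. This is the plain CPM transform; no between-library
#' scaling-factor normalization (e.g. TMM) is applied.
#'
#' @param counts A [SegmentCounts], or a non-negative numeric matrix with
#'   gene rownames and segment colnames.
#' @param prior Non-negative pseudo-count added to CPM before the log
#'   (default 1).
#' @return A [SegmentExperiment] of log2 CPM values.
#' @examples
#' cts <- matrix(c(1, 3), 2, 1, dimnames = list(c("g1", "g2"), "S1"))
#' exprValues(log2CPM(cts))  # log2(c(250000, 750000) + 1)
#' @export
log2CPM <- function(counts, prior = 1) {
  if (is.matrix(counts)) counts <- SegmentCounts(counts)
  if (!is(counts, "SegmentCounts"))
    .segStop("badArgument", "'counts' must be a SegmentCounts or numeric matrix")
  if (!is.numeric(prior) || length(prior) != 1L || is.na(prior) || prior < 0)
    .segStop("badArgument", "'prior' must be a single non-negative number")
  m <- assay(counts, "counts")
  libsize <- colSums(m)
  # validity guarantees libsize > 0; prior = 0 with zero counts would give -Inf
  cpm <- sweep(m, 2L, libsize, "/") * 1e6
  v <- log2(cpm + prior)
  if (any(!is.finite(v)))
    .segStop("nonFiniteValue",
             "log2 CPM produced non-finite values (zero counts with prior = 0?)")
  SegmentExperiment(v)
}

#' Scale a gene's per-segment values to the unit interval
#'
#' The scaling behind the color mapping. In `"normalized"` view each gene is
#' min-max scaled across segments (its own minimum maps to 0, maximum to 1),
#' which emphasises the spatial pattern regardless of expression magnitude. In
#' `"absolute"` view values are scaled against a dataset-wide range
#' (`datasetRange`), clamped to \[0, 1\], preserving cross-gene magnitude
#' differences. A zero-variance (flat) gene maps to 0.5 everywhere in
#' normalized view; the result then carries attribute `zeroVariance = TRUE`
#' and a warning is issued — flat housekeeping genes still render, at
#' mid-scale.
#'
#' @param values Numeric vector of per-segment values (length >= 1, finite).
#' @param mode `"normalized"` or `"absolute"`.
#' @param datasetRange Numeric length-2 `(min, max)`; required and
#'   non-degenerate for absolute mode.
#' @return Numeric vector in \[0, 1\], same length and names as `values`;
#'   attribute `zeroVariance` is `TRUE` for a flat gene in normalized view.
#' @examples
#' normalizeGene(c(2, 4, 6), "normalized")          # 0, 0.5, 1
#' normalizeGene(c(2, 5), "absolute", c(0, 10))     # 0.2, 0.5
#' @export
normalizeGene <- function(values, mode = c("normalized", "absolute"),
                          datasetRange = NULL) {
  mode <- viewMode(mode)
  if (length(values) < 1L || any(!is.finite(values)))
    .segStop("badArgument", "'values' must be a non-empty finite numeric vector")
  if (mode == "normalized") {
    if (.isConstant(values)) {
      warning(sprintf("zero-variance values; mapping to mid-scale 0.5"),
              call. = FALSE)
      out <- rep(0.5, length(values))
      names(out) <- names(values)
      attr(out, "zeroVariance") <- TRUE
      return(out)
    }
    out <- .minMax(values)
  } else {
    if (is.null(datasetRange) || length(datasetRange) != 2L ||
        any(!is.finite(datasetRange)))
      .segStop("badArgument",
               "absolute mode requires a finite datasetRange = c(min, max)")
    if (datasetRange[1L] == datasetRange[2L])
      .segStop("degenerateRange",
               "absolute mode requires dataset min < max")
    out <- (values - datasetRange[1L]) / (datasetRange[2L] - datasetRange[1L])
    out <- pmin(1, pmax(0, out))
  }
  names(out) <- names(values)
  attr(out, "zeroVariance") <- FALSE
  out
}
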