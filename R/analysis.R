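## Synexpression analysis: similarity ranking, heatmap differences, and
## region-of-interest group contrasts.

#' Similarity of two expression patterns, as a percentage
#'
#' The atlas similarity statistic: the absolute Pearson correlation of two
#' per-segment expression vectors, scaled to \[0, 100\]. Because the absolute
#' value is taken, perfectly anti-correlated patterns also score 100 — the
#' ranking retrieves synexpression in either orientation. The score is
#' invariant under affine maps `v -> a*v + b` (a != 0) of either argument and
#' symmetric in its arguments. Undefined for constant vectors.
#'
#' @param x,y Numeric vectors of equal length >= 3, finite.
#' @return Score in \[0, 100\].
#' @examples
#' similarityScore(c(1, 2, 3), c(2, 4, 6))  # 100
#' similarityScore(c(1, 2, 3), c(3, 2, 1))  # 100 (anti-correlation counts)
#' similarityScore(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 80
#' @export
similarityScore <- function(x, y) {
  if (length(x) != length(y))
    .segStop("badArgument", "vectors must have equal length")
  if (length(x) < 3L)
    .segStop("badArgument", "at least 3 segments required for a correlation")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    .segStop("badArgument", "vectors must be finite")
  if (.isConstant(x) || .isConstant(y))
    .segStop("zeroVariance",
             "correlation undefined for a constant expression vector")
  min(100, 100 * abs(stats::cor(x, y)))
}

# internal: rank candidate rows against a target vector; returns a
# SimilarityTable. `candidates` is a genes x segments matrix.
.rankAgainst <- function(candidates, target, query, k, mode) {
  keep <- apply(candidates, 1L, function(r) !.isConstant(r))
  skipped <- rownames(candidates)[!keep]
  scored <- candidates[keep, , drop = FALSE]
  if (nrow(scored)) {
    # one matrix-vector correlation pass; equivalent to per-row cor()
    r <- as.numeric(stats::cor(t(scored), target))
    score <- pmin(100, 100 * abs(r))
    ord <- order(-score, rownames(scored))
    genes <- rownames(scored)[ord]
    score <- score[ord]
  } else {
    genes <- character()
    score <- numeric()
  }
  if (is.finite(k)) {
    k <- as.integer(k)
    if (k < 1L) .segStop("badArgument", "'k' must be a positive integer")
    genes <- head(genes, k)
    score <- head(score, k)
  }
  new("SimilarityTable", query = query,
      records = DataFrame(gene = genes, similarity_percent = score),
      mode = "normalized", skipped = sort(skipped))
}

#' Rank genes by similarity to a query gene
#'
#' Scores every other gene in the dataset against the query's per-segment
#' log2 CPM profile with [similarityScore()] (absolute Pearson correlation as
#' a percentage) and returns the top `k`, sorted by descending score with
#' ties broken by gene ID. Genes with constant expression across segments
#' have undefined correlation and are reported in the table's skipped list
#' instead of being ranked. The score is symmetric: gene A ranks B exactly as
#' B ranks A.
#'
#' @param x A [SegmentExperiment].
#' @param query Gene ID present in `x`.
#' @param k Number of records to keep (default `Inf` = all).
#' @return A [SimilarityTable] (query excluded from its own ranking).
#' @seealso [groupContrast()] for ranking against a region template.
#' @export
similarGenes <- function(x, query, k = Inf) {
  stopifnot(is(x, "SegmentExperiment"))
  .assertScalarString(query, "query")
  m <- exprValues(x)
  if (!query %in% rownames(m))
    .segStop("unknownGene", sprintf("query gene '%s' not in dataset", query))
  if (ncol(m) < 3L)
    .segStop("badArgument", "at least 3 segments required")
  q <- m[query, ]
  if (.isConstant(q))
    .segStop("queryZeroVariance",
             sprintf("query gene '%s' is constant across segments", query))
  .rankAgainst(m[setdiff(rownames(m), query), , drop = FALSE], q, query, k,
               mode = "normalized")
}

#' Per-segment expression difference of two genes (heatmap comparison)
#'
#' For each segment computes the absolute difference of the two genes'
#' values: raw log2 CPM in `"absolute"` view, or per-gene min-max normalized
#' values in `"normalized"` view (so two genes with the same spatial shape at
#' different magnitudes show zero difference). The diff vector is then
#' min-max scaled through the palette: the segment with the largest
#' difference is colored exactly the high color (red by default), the
#' smallest exactly the low color (blue). Identical (mode-transformed)
#' profiles — including comparing a gene with itself — give an all-zero diff
#' vector, colored uniformly at the palette midpoint.
#'
#' @param x A [SegmentExperiment].
#' @param geneA,geneB Gene IDs present in `x`.
#' @param mode `"normalized"` or `"absolute"`.
#' @param palette A [Palette] for the diff colors.
#' @return A [HeatmapResult].
#' @export
heatmapDiff <- function(x, geneA, geneB, mode = c("normalized", "absolute"),
                        palette = segPalette("default")) {
  stopifnot(is(x, "SegmentExperiment"))
  mode <- viewMode(mode)
  .assertScalarString(geneA, "geneA")
  .assertScalarString(geneB, "geneB")
  m <- exprValues(x)
  for (g in c(geneA, geneB))
    if (!g %in% rownames(m))
      .segStop("unknownGene", sprintf("gene '%s' not in dataset", g))
  va <- m[geneA, ]
  vb <- m[geneB, ]
  if (mode == "normalized") {
    # flat genes sit at mid-scale, consistent with their rendering
    va <- if (.isConstant(va)) rep(0.5, length(va)) else .minMax(va)
    vb <- if (.isConstant(vb)) rep(0.5, length(vb)) else .minMax(vb)
  }
  diffs <- abs(va - vb)
  t <- .minMax(diffs)  # constant diffs (incl. all zero) -> 0.5 mid color
  cm <- .colorMapFromUnit(t, segmentIds(x),
                          sprintf("|%s-%s|", geneA, geneB), mode, palette)
  new("HeatmapResult", geneA = geneA, geneB = geneB,
      segmentIds = segmentIds(x), diffs = as.numeric(diffs), colors = cm,
      mode = mode)
}

#' Rank genes by match to a two-region contrast
#'
#' Builds a binary template over the selected segments — 1 on group A, 0 on
#' group B — and scores every gene, restricted to those segments, with
#' [similarityScore()] against the template. A gene uniformly high in one
#' region and low in the other scores 100 regardless of which region is
#' which (the absolute correlation is invariant under swapping the groups).
#' Genes constant over the selected segments are skipped. Segments outside
#' the selection do not influence the ranking.
#'
#' @param x A [SegmentExperiment].
#' @param selection A [GroupSelection]; all its segment IDs must exist in `x`.
#' @param k Number of records to keep (default `Inf` = all).
#' @param method `"correlation"` (the atlas statistic) or `"mean_diff"`, a
#'   secondary score: the absolute difference of the two group means after
#'   min-max normalizing each gene over the selected segments, as a
#'   percentage.
#' @return A [SimilarityTable] with query `"group-template"`.
#' @export
groupContrast <- function(x, selection, k = Inf,
                          method = c("correlation", "mean_diff")) {
  stopifnot(is(x, "SegmentExperiment"))
  method <- match.arg(method)
  if (!is(selection, "GroupSelection"))
    .segStop("badArgument", "'selection' must be a GroupSelection")
  validObject(selection)
  segs <- segmentIds(x)
  unknown <- setdiff(c(selection@groupA, selection@groupB), segs)
  if (length(unknown))
    .segStop("unknownSegment",
             sprintf("segment ID(s) not in dataset: %s",
                     paste(unknown, collapse = ", ")))
  sel <- c(selection@groupA, selection@groupB)
  if (length(sel) < 3L)
    .segStop("badArgument",
             "at least 3 selected segments required for a correlation")
  template <- c(rep(1, length(selection@groupA)),
                rep(0, length(selection@groupB)))
  m <- exprValues(x)[, sel, drop = FALSE]
  if (method == "correlation")
    return(.rankAgainst(m, template, "group-template", k, mode = "normalized"))
  # mean_diff: min-max normalize each gene over selected segments, then
  # |mean(group A) - mean(group B)| * 100
  keep <- apply(m, 1L, function(r) !.isConstant(r))
  skipped <- rownames(m)[!keep]
  scored <- m[keep, , drop = FALSE]
  inA <- seq_along(selection@groupA)
  score <- apply(scored, 1L, function(r) {
    u <- .minMax(r)
    100 * abs(mean(u[inA]) - mean(u[-inA]))
  })
  ord <- order(-score, rownames(scored))
  genes <- rownames(scored)[ord]
  score <- score[ord]
  if (is.finite(k)) {
    genes <- head(genes, as.integer(k))
    score <- head(score, as.integer(k))
  }
  new("SimilarityTable", query = "group-template",
      records = DataFrame(gene = genes, similarity_percent = score),
      mode = "normalized", skipped = sort(skipped))
}
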