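#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## ---------------------------------------------------------------------------
## Expression containers
## ---------------------------------------------------------------------------

#' SegmentExperiment: log2 CPM expression across anatomical segments
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one assay,
#' `"log2cpm"`: a genes-by-segments matrix of log2 counts-per-million values.
#' Row names are unique gene IDs; column names are unique segment IDs in the
#' canonical model order (the order in which segments appear in the matched 3D
#' model). Values must be finite; log2 CPM of lowly expressed genes may be
#' negative.
#'
#' @aliases SegmentExperiment-class
#' @export
setClass("SegmentExperiment", contains = "SummarizedExperiment")

setValidity("SegmentExperiment", function(object) {
  msg <- character()
  if (!"log2cpm" %in% assayNames(object))
    msg <- c(msg, "assay 'log2cpm' is required")
  else {
    m <- assay(object, "log2cpm")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)) || any(!nzchar(rownames(m))))
      msg <- c(msg, "gene IDs (rownames) must be unique and non-empty")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)) || any(!nzchar(colnames(m))))
      msg <- c(msg, "segment IDs (colnames) must be unique and non-empty")
    if (!all(is.finite(m)))
      msg <- c(msg, "all expression values must be finite (no NA/NaN/Inf)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SegmentExperiment from a genes-by-segments matrix
#'
#' @param values Numeric matrix, genes in rows (unique rownames), segments in
#'   columns (unique colnames, canonical order), log2 CPM units.
#' @return A [SegmentExperiment].
#' @examples
#' m <- matrix(rnorm(6, 4), 2, 3,
#'             dimnames = list(c("Myh6", "Nppa"), c("S1", "S2", "S3")))
#' SegmentExperiment(m)
#' @export
SegmentExperiment <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    .segStop("badArgument", "'values' must be a numeric matrix")
  se <- SummarizedExperiment(assays = list(log2cpm = values))
  new("SegmentExperiment", se)
}

#' SegmentCounts: raw per-segment library counts
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass with one assay
#' `"counts"` of non-negative raw counts; each segment (library) must have a
#' positive total count so counts-per-million is defined.
#'
#' @aliases SegmentCounts-class
#' @export
setClass("SegmentCounts", contains = "SummarizedExperiment")

setValidity("SegmentCounts", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (any(!is.finite(m)) || any(m < 0))
      msg <- c(msg, "counts must be finite and non-negative")
    else if (any(colSums(m) <= 0))
      msg <- c(msg, "every segment library must have total count > 0")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
      msg <- c(msg, "gene IDs (rownames) must be unique")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
      msg <- c(msg, "segment IDs (colnames) must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SegmentCounts object
#'
#' @param counts Non-negative numeric matrix with gene rownames and segment
#'   colnames; column sums must be positive.
#' @return A [SegmentCounts].
#' @export
SegmentCounts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    .segStop("badArgument", "'counts' must be a numeric matrix")
  if (any(!is.finite(counts)) || any(counts < 0))
    .segStop("negativeCounts", "counts must be finite and non-negative")
  if (any(colSums(counts) <= 0)) {
    bad <- colnames(counts)[colSums(counts) <= 0]
    .segStop("emptyLibrary",
             sprintf("segment librar%s with zero total count: %s",
                     if (length(bad) > 1) "ies" else "y",
                     paste(bad, collapse = ", ")))
  }
  se <- SummarizedExperiment(assays = list(counts = counts))
  new("SegmentCounts", se)
}

#' @describeIn segmentIds Segment IDs (column names) of an expression container.
#' @export
setMethod("segmentIds", "SummarizedExperiment", function(x) colnames(x))

#' @describeIn nSegments Number of segments (columns) of an expression container.
#' @export
setMethod("nSegments", "SummarizedExperiment", function(x) ncol(x))

#' Gene identifiers of an expression container
#' @param x A [SegmentExperiment] or [SegmentCounts].
#' @return Character vector of gene IDs.
#' @export
geneIds <- function(x) rownames(x)

#' Expression values of a SegmentExperiment
#' @param x A [SegmentExperiment].
#' @return The genes-by-segments log2 CPM matrix.
#' @export
exprValues <- function(x) {
  stopifnot(is(x, "SegmentExperiment"))
  assay(x, "log2cpm")
}

## ---------------------------------------------------------------------------
## Palettes and color maps
## ---------------------------------------------------------------------------

#' Palette: two-endpoint linear color gradient
#'
#' Expression is colored by linear interpolation between a low and a high
#' endpoint in RGB space. The default atlas palette runs blue (low) to red
#' (high); the color-vision-deficiency (CVD) palette runs blue to yellow.
#'
#' @slot name Palette name, `"default"` or `"cvd"` (or `"custom"`).
#' @slot low Integer RGB triple in \[0, 255\] for the low endpoint.
#' @slot high Integer RGB triple for the high endpoint.
#' @aliases Palette-class
#' @export
setClass("Palette", representation(name = "character",
                                   low = "integer",
                                   high = "integer"))

setValidity("Palette", function(object) {
  msg <- character()
  for (s in c("low", "high")) {
    v <- slot(object, s)
    if (length(v) != 3L || any(is.na(v)) || any(v < 0L) || any(v > 255L))
      msg <- c(msg, sprintf("'%s' must be an RGB triple of integers in [0,255]", s))
  }
  if (length(object@name) != 1L) msg <- c(msg, "'name' must be a single string")
  if (length(msg)) msg else TRUE
})

#' Built-in atlas palettes
#'
#' @param name `"default"` (blue \eqn{\to} red) or `"cvd"` (blue \eqn{\to}
#'   yellow, for color-vision deficiency).
#' @return A [Palette].
#' @examples
#' segPalette("default")
#' segPalette("cvd")
#' @export
segPalette <- function(name = c("default", "cvd")) {
  name <- match.arg(name)
  switch(name,
         default = new("Palette", name = "default",
                       low = c(0L, 0L, 255L), high = c(255L, 0L, 0L)),
         cvd = new("Palette", name = "cvd",
                   low = c(0L, 0L, 255L), high = c(255L, 255L, 0L)))
}

setMethod("show", "Palette", function(object) {
  cat(sprintf("Palette '%s': rgb(%s) -> rgb(%s)\n", object@name,
              paste(object@low, collapse = ","),
              paste(object@high, collapse = ",")))
})

#' SegmentColorMap: one RGB color per segment
#'
#' The result of mapping one gene's (or one diff vector's) values through a
#' palette: an ordered set of segment IDs with one 8-bit RGB color each, plus
#' provenance (source gene, view mode, palette).
#'
#' @slot segmentIds Ordered segment IDs.
#' @slot colors Integer matrix, segments x 3 (R, G, B in \[0, 255\]).
#' @slot sourceGene Gene (or comparison) the colors were derived from.
#' @slot mode View mode used (`"normalized"` or `"absolute"`).
#' @slot palette The [Palette] used.
#' @aliases SegmentColorMap-class
#' @export
setClass("SegmentColorMap", representation(segmentIds = "character",
                                           colors = "matrix",
                                           sourceGene = "character",
                                           mode = "character",
                                           palette = "Palette"))

setValidity("SegmentColorMap", function(object) {
  msg <- character()
  if (anyDuplicated(object@segmentIds))
    msg <- c(msg, "segment IDs must be unique")
  if (nrow(object@colors) != length(object@segmentIds) || ncol(object@colors) != 3L)
    msg <- c(msg, "colors must be a segments x 3 matrix")
  else if (any(is.na(object@colors)) || any(object@colors < 0) || any(object@colors > 255))
    msg <- c(msg, "color channels must lie in [0, 255]")
  if (length(msg)) msg else TRUE
})

#' @describeIn segmentIds Segment IDs of a color map.
#' @export
setMethod("segmentIds", "SegmentColorMap", function(x) x@segmentIds)

#' @describeIn nSegments Number of segments of a color map.
#' @export
setMethod("nSegments", "SegmentColorMap", function(x) length(x@segmentIds))

#' Per-segment RGB colors of a color map
#' @param x A [SegmentColorMap].
#' @return Integer matrix segments x 3 with rownames = segment IDs.
#' @export
segmentColors <- function(x) {
  stopifnot(is(x, "SegmentColorMap"))
  m <- x@colors
  rownames(m) <- x@segmentIds
  m
}

#' Hex representation of a color map's colors
#' @param x A [SegmentColorMap].
#' @return Character vector of `#RRGGBB` strings, named by segment.
#' @export
segmentHexColors <- function(x) {
  m <- segmentColors(x)
  stats::setNames(sprintf("#%02X%02X%02X", m[, 1], m[, 2], m[, 3]), rownames(m))
}

setMethod("show", "SegmentColorMap", function(object) {
  cat(sprintf("SegmentColorMap for '%s' (%s view, %s palette), %d segments\n",
              object@sourceGene, object@mode, object@palette@name,
              length(object@segmentIds)))
  hx <- segmentHexColors(object)
  n <- min(6L, length(hx))
  cat("  ", paste(sprintf("%s=%s", names(hx)[seq_len(n)], hx[seq_len(n)]),
                  collapse = " "),
      if (length(hx) > n) "..." else "", "\n")
})

## ---------------------------------------------------------------------------
## Segmented meshes
## ---------------------------------------------------------------------------

#' SegmentedModel: named per-segment triangle meshes in one frame
#'
#' An ordered collection of triangle meshes, one per anatomical segment, all
#' sharing one right-handed (y-up) coordinate frame. Each segment is a list
#' with a `vertices` matrix (n x 3) and a 1-based `faces` integer matrix
#' (m x 3). Segment order is the canonical model order (order of first
#' appearance in the OBJ file).
#'
#' @slot segmentIds Ordered unique segment names.
#' @slot meshes List parallel to `segmentIds`; each element is
#'   `list(vertices = <n x 3 numeric>, faces = <m x 3 integer>)`.
#' @aliases SegmentedModel-class
#' @export
setClass("SegmentedModel", representation(segmentIds = "character",
                                          meshes = "list"))

setValidity("SegmentedModel", function(object) {
  msg <- character()
  if (anyDuplicated(object@segmentIds))
    msg <- c(msg, "segment IDs must be unique")
  if (length(object@meshes) != length(object@segmentIds))
    msg <- c(msg, "one mesh per segment ID required")
  for (i in seq_along(object@meshes)) {
    mesh <- object@meshes[[i]]
    if (!is.list(mesh) || !all(c("vertices", "faces") %in% names(mesh))) {
      msg <- c(msg, sprintf("segment %d lacks vertices/faces", i)); next
    }
    v <- mesh$vertices; f <- mesh$faces
    if (!is.matrix(v) || ncol(v) != 3L || !is.numeric(v))
      msg <- c(msg, sprintf("segment '%s': vertices must be an n x 3 numeric matrix",
                            object@segmentIds[i]))
    if (!is.matrix(f) || ncol(f) != 3L)
      msg <- c(msg, sprintf("segment '%s': faces must be an m x 3 index matrix",
                            object@segmentIds[i]))
    else {
      if (nrow(f) == 0L)
        msg <- c(msg, sprintf("segment '%s' has no faces", object@segmentIds[i]))
      if (nrow(f) > 0 && (min(f) < 1L || max(f) > nrow(v)))
        msg <- c(msg, sprintf("segment '%s': face indices out of range",
                              object@segmentIds[i]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SegmentedModel
#' @param segmentIds Character vector of unique segment names.
#' @param meshes List of `list(vertices, faces)` parallel to `segmentIds`.
#' @return A [SegmentedModel].
#' @export
SegmentedModel <- function(segmentIds, meshes) {
  meshes <- lapply(meshes, function(m) {
    m$vertices <- matrix(as.numeric(m$vertices), ncol = 3L,
                         nrow = nrow(m$vertices))
    m$faces <- matrix(as.integer(m$faces), ncol = 3L, nrow = nrow(m$faces))
    m[c("vertices", "faces")]
  })
  new("SegmentedModel", segmentIds = as.character(segmentIds), meshes = meshes)
}

#' @describeIn segmentIds Segment IDs of a segmented mesh.
#' @export
setMethod("segmentIds", "SegmentedModel", function(x) x@segmentIds)

#' @describeIn nSegments Number of segments of a segmented mesh.
#' @export
setMethod("nSegments", "SegmentedModel", function(x) length(x@segmentIds))

#' Per-segment meshes of a SegmentedModel
#' @param x A [SegmentedModel].
#' @return Named list of `list(vertices, faces)`.
#' @export
segmentMeshes <- function(x) {
  stopifnot(is(x, "SegmentedModel"))
  stats::setNames(x@meshes, x@segmentIds)
}

setMethod("show", "SegmentedModel", function(object) {
  nv <- vapply(object@meshes, function(m) nrow(m$vertices), integer(1))
  nf <- vapply(object@meshes, function(m) nrow(m$faces), integer(1))
  cat(sprintf("SegmentedModel: %d segments, %d vertices, %d triangles\n",
              length(object@segmentIds), sum(nv), sum(nf)))
  n <- min(6L, length(object@segmentIds))
  cat("  segments:", paste(object@segmentIds[seq_len(n)], collapse = ", "),
      if (length(object@segmentIds) > n) "..." else "", "\n")
})

#' ColoredModel: a segmented mesh with per-segment vertex colors
#'
#' Pairs a [SegmentedModel] with a [SegmentColorMap]; every vertex of a
#' segment carries that segment's uniform color (the headless equivalent of
#' the colored organ model in the interactive atlas).
#'
#' @slot model The [SegmentedModel].
#' @slot colorMap The [SegmentColorMap]; its segment IDs must match the
#'   model's as a set.
#' @aliases ColoredModel-class
#' @export
setClass("ColoredModel", representation(model = "SegmentedModel",
                                        colorMap = "SegmentColorMap"))

setValidity("ColoredModel", function(object) {
  if (!setequal(segmentIds(object@model), segmentIds(object@colorMap)))
    "model and color map segment IDs must match as a set"
  else TRUE
})

#' @describeIn segmentIds Segment IDs of a colored model (model order).
#' @export
setMethod("segmentIds", "ColoredModel", function(x) segmentIds(x@model))

#' @describeIn nSegments Number of segments of a colored model.
#' @export
setMethod("nSegments", "ColoredModel", function(x) nSegments(x@model))

#' The mesh of a ColoredModel
#' @param x A [ColoredModel].
#' @return The underlying [SegmentedModel].
#' @export
coloredMesh <- function(x) { stopifnot(is(x, "ColoredModel")); x@model }

#' The color map of a ColoredModel
#' @param x A [ColoredModel].
#' @return The underlying [SegmentColorMap].
#' @export
coloredMap <- function(x) { stopifnot(is(x, "ColoredModel")); x@colorMap }

setMethod("show", "ColoredModel", function(object) {
  cat("ColoredModel\n")
  show(object@model)
  show(object@colorMap)
})

## ---------------------------------------------------------------------------
## Analysis results
## ---------------------------------------------------------------------------

#' SimilarityTable: ranked co-expression matches for a query
#'
#' Genes ranked by similarity to a query gene (or to a binary group template),
#' where similarity is the absolute Pearson correlation of per-segment
#' expression, expressed as a percentage in \[0, 100\]. Records are sorted by
#' descending score with ties broken by gene ID; the query itself is excluded.
#' Genes whose expression is constant over the scored segments have undefined
#' correlation and are listed in `skipped` rather than ranked.
#'
#' @slot query Query gene ID, or `"group-template"` for group contrasts.
#' @slot records A [S4Vectors::DataFrame] with columns `gene` and
#'   `similarity_percent`.
#' @slot mode View mode the scores refer to.
#' @slot skipped Gene IDs excluded for zero variance.
#' @aliases SimilarityTable-class
#' @export
setClass("SimilarityTable", representation(query = "character",
                                           records = "DataFrame",
                                           mode = "character",
                                           skipped = "character"))

setValidity("SimilarityTable", function(object) {
  msg <- character()
  r <- object@records
  if (!all(c("gene", "similarity_percent") %in% colnames(r)))
    msg <- c(msg, "records must have columns 'gene' and 'similarity_percent'")
  else {
    s <- r$similarity_percent
    if (length(s) && (any(s < -1e-9) || any(s > 100 + 1e-9)))
      msg <- c(msg, "scores must lie in [0, 100]")
    if (length(s) > 1) {
      ord <- order(-s, r$gene)
      if (!identical(ord, seq_along(s)))
        msg <- c(msg, "records must be sorted by descending score, ties by gene ID")
    }
    if (any(r$gene == object@query))
      msg <- c(msg, "query must be excluded from records")
  }
  if (length(msg)) msg else TRUE
})

#' Records of a SimilarityTable as a data.frame
#' @param x A [SimilarityTable].
#' @return data.frame with columns `rank`, `gene`, `similarity_percent`.
#' @export
similarityRecords <- function(x) {
  stopifnot(is(x, "SimilarityTable"))
  df <- as.data.frame(x@records)
  if (nrow(df)) df <- cbind(rank = seq_len(nrow(df)), df)
  else df <- data.frame(rank = integer(), gene = character(),
                        similarity_percent = numeric())
  df
}

#' Genes skipped from a ranking for zero variance
#' @param x A [SimilarityTable].
#' @return Character vector of gene IDs.
#' @export
skippedGenes <- function(x) { stopifnot(is(x, "SimilarityTable")); x@skipped }

setMethod("show", "SimilarityTable", function(object) {
  cat(sprintf("SimilarityTable: query '%s' (%s view), %d ranked, %d skipped\n",
              object@query, object@mode, nrow(object@records),
              length(object@skipped)))
  df <- similarityRecords(object)
  print(head(df, 5))
  if (nrow(df) > 5) cat("  ...\n")
})

#' GroupSelection: a two-region contrast of segments
#'
#' Two disjoint, non-empty sets of segment IDs defining a region-of-interest
#' contrast (e.g. atria vs ventricles). Used by [groupContrast()] to rank
#' genes whose expression separates the two regions.
#'
#' @slot groupA Segment IDs of the first region.
#' @slot groupB Segment IDs of the second region.
#' @aliases GroupSelection-class
#' @export
setClass("GroupSelection", representation(groupA = "character",
                                          groupB = "character"))

setValidity("GroupSelection", function(object) {
  msg <- character()
  if (length(object@groupA) == 0L || length(object@groupB) == 0L)
    msg <- c(msg, "both groups must be non-empty")
  if (length(intersect(object@groupA, object@groupB)))
    msg <- c(msg, "groups must be disjoint")
  if (anyDuplicated(object@groupA) || anyDuplicated(object@groupB))
    msg <- c(msg, "segment IDs within a group must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a GroupSelection
#' @param groupA,groupB Character vectors of segment IDs; disjoint, non-empty.
#' @return A [GroupSelection].
#' @examples
#' GroupSelection(c("S1", "S2"), c("S10", "S11"))
#' @export
GroupSelection <- function(groupA, groupB) {
  if (length(groupA) == 0L)
    .segStop("emptyGroup", "group A is empty")
  if (length(groupB) == 0L)
    .segStop("emptyGroup", "group B is empty")
  if (length(intersect(groupA, groupB)))
    .segStop("overlappingGroups",
             sprintf("groups overlap: %s",
                     paste(intersect(groupA, groupB), collapse = ", ")))
  new("GroupSelection", groupA = as.character(groupA),
      groupB = as.character(groupB))
}

setMethod("show", "GroupSelection", function(object) {
  cat(sprintf("GroupSelection: A = {%s} vs B = {%s}\n",
              paste(object@groupA, collapse = ","),
              paste(object@groupB, collapse = ",")))
})

#' HeatmapResult: per-segment expression difference of two genes
#'
#' For each segment, the absolute difference of the two genes' values (raw
#' log2 CPM in absolute view; per-gene min-max normalized in normalized view),
#' plus the color map obtained by min-max scaling the diff vector through a
#' palette, so the segment with the largest difference is exactly the high
#' color and the smallest exactly the low color.
#'
#' @slot geneA,geneB The two compared genes.
#' @slot segmentIds Ordered segment IDs.
#' @slot diffs Non-negative per-segment differences.
#' @slot colors The [SegmentColorMap] over the diff vector.
#' @slot mode View mode used.
#' @aliases HeatmapResult-class
#' @export
setClass("HeatmapResult", representation(geneA = "character",
                                         geneB = "character",
                                         segmentIds = "character",
                                         diffs = "numeric",
                                         colors = "SegmentColorMap",
                                         mode = "character"))

setValidity("HeatmapResult", function(object) {
  msg <- character()
  if (length(object@diffs) != length(object@segmentIds))
    msg <- c(msg, "one diff per segment required")
  if (any(object@diffs < 0))
    msg <- c(msg, "diffs must be non-negative")
  if (!identical(object@colors@segmentIds, object@segmentIds))
    msg <- c(msg, "color map segments must match diff segments")
  if (length(msg)) msg else TRUE
})

#' Per-segment differences of a HeatmapResult
#' @param x A [HeatmapResult].
#' @return Named numeric vector of non-negative differences.
#' @export
heatmapDiffs <- function(x) {
  stopifnot(is(x, "HeatmapResult"))
  stats::setNames(x@diffs, x@segmentIds)
}

#' Color map of a HeatmapResult
#' @param x A [HeatmapResult].
#' @return The [SegmentColorMap] over the diff vector.
#' @export
heatmapColors <- function(x) { stopifnot(is(x, "HeatmapResult")); x@colors }

setMethod("show", "HeatmapResult", function(object) {
  cat(sprintf("HeatmapResult: |%s - %s| per segment (%s view)\n",
              object@geneA, object@geneB, object@mode))
  print(head(heatmapDiffs(object), 6))
})

#' @describeIn segmentIds Segment IDs of a heatmap result.
#' @export
setMethod("segmentIds", "HeatmapResult", function(x) x@segmentIds)

## ---------------------------------------------------------------------------
## Session log
## ---------------------------------------------------------------------------

.sessionActions <- c("select_gene", "compare_side_by_side", "heatmap",
                     "group_contrast", "snapshot", "export")

#' SessionLog: chronological record of atlas actions
#'
#' An append-only list of visualization/comparison events, each carrying a
#' UTC ISO-8601 timestamp (millisecond precision), the action, the gene(s)
#' involved, the view mode, and a model identifier — the headless equivalent
#' of the backup file the interactive atlas writes during a session.
#' Timestamps must be non-decreasing; events can only be appended.
#'
#' @slot events data.frame with columns `timestamp`, `action`, `genes`,
#'   `view_mode`, `model_id` (all character; `genes` joins multiple genes
#'   with `;`).
#' @aliases SessionLog-class
#' @export
setClass("SessionLog", representation(events = "data.frame"))

.sessionCols <- c("timestamp", "action", "genes", "view_mode", "model_id")

setValidity("SessionLog", function(object) {
  ev <- object@events
  msg <- character()
  if (!identical(colnames(ev), .sessionCols))
    msg <- c(msg, sprintf("events must have columns: %s",
                          paste(.sessionCols, collapse = ", ")))
  else {
    if (nrow(ev) && !all(ev$action %in% .sessionActions))
      msg <- c(msg, "unknown action in events")
    if (nrow(ev) > 1 && is.unsorted(ev$timestamp))
      msg <- c(msg, "timestamps must be non-decreasing")
  }
  if (length(msg)) msg else TRUE
})

#' Create an empty SessionLog
#' @return A [SessionLog] with no events.
#' @export
SessionLog <- function() {
  ev <- data.frame(timestamp = character(), action = character(),
                   genes = character(), view_mode = character(),
                   model_id = character(), stringsAsFactors = FALSE)
  new("SessionLog", events = ev)
}

#' Events of a SessionLog
#' @param x A [SessionLog].
#' @return data.frame of events in chronological order.
#' @export
sessionEvents <- function(x) { stopifnot(is(x, "SessionLog")); x@events }

setMethod("show", "SessionLog", function(object) {
  cat(sprintf("SessionLog: %d events\n", nrow(object@events)))
  if (nrow(object@events)) print(utils::tail(object@events, 5))
})

#' @importFrom utils tail
NULL
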