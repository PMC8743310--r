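## Synthetic data: expression matrices with planted spatial patterns and a
## segmented block mesh, so the whole pipeline is testable without the
## released organ dataset.

#' Planted expression pattern specifications
#'
#' Constructors for the pattern kinds the generator can plant into a
#' synthetic expression matrix. All values are on the log2 CPM scale
#' convention (`baseline` is a typical moderate expression level; `amplitude`
#' is the spatial signal in log2 units, so amplitude 5 is a ~32-fold
#' regional difference).
#'
#' * `uniformPattern()`: flat at `baseline` in every segment.
#' * `markerPattern(segments)`: `baseline + amplitude` on the listed
#'   segments, `baseline` elsewhere — a regional marker.
#' * `gradientPattern()`: linear ramp from `baseline` to
#'   `baseline + amplitude` along the canonical segment order.
#' * `copyOfPattern(gene, scale, offset)`: affine image
#'   `scale * source + offset` of another planted gene's noiseless pattern —
#'   a perfect synexpression partner.
#' * `groupTemplatePattern(groupA, groupB)`: `baseline + amplitude` on
#'   `groupA`, `baseline` on `groupB` and elsewhere — matches a
#'   [GroupSelection] contrast exactly.
#'
#' @param baseline Baseline log2 CPM level (default 4).
#' @param amplitude Spatial signal amplitude in log2 units (>= 0, default 5).
#' @param segments,groupA,groupB Segment IDs the pattern refers to.
#' @param gene Gene ID of the source pattern to copy.
#' @param scale,offset Affine parameters of the copy.
#' @return A `PatternSpec` list understood by [makeSyntheticExpression()].
#' @name patternSpecs
NULL

.patternSpec <- function(kind, baseline, amplitude, ...) {
  if (!is.numeric(amplitude) || amplitude < 0)
    .segStop("badPattern", "'amplitude' must be non-negative")
  structure(list(kind = kind, baseline = baseline, amplitude = amplitude, ...),
            class = "PatternSpec")
}

#' @rdname patternSpecs
#' @export
uniformPattern <- function(baseline = 4) {
  .patternSpec("uniform", baseline, 0)
}

#' @rdname patternSpecs
#' @export
markerPattern <- function(segments, baseline = 4, amplitude = 5) {
  .patternSpec("marker", baseline, amplitude, segments = as.character(segments))
}

#' @rdname patternSpecs
#' @export
gradientPattern <- function(baseline = 4, amplitude = 5) {
  .patternSpec("gradient", baseline, amplitude)
}

#' @rdname patternSpecs
#' @export
copyOfPattern <- function(gene, scale = 1, offset = 0) {
  if (!is.numeric(scale) || scale == 0)
    .segStop("badPattern", "'scale' must be non-zero")
  .patternSpec("copy_of", NA_real_, 0, source = gene, scale = scale,
               offset = offset)
}

#' @rdname patternSpecs
#' @export
groupTemplatePattern <- function(groupA, groupB, baseline = 4, amplitude = 5) {
  if (length(intersect(groupA, groupB)))
    .segStop("badPattern", "groups of a group_template pattern must be disjoint")
  .patternSpec("group_template", baseline, amplitude,
               groupA = as.character(groupA), groupB = as.character(groupB))
}

# noiseless per-segment values of a pattern; `resolved` holds previously
# resolved pattern values for copy_of sources
.patternValues <- function(spec, segIds, resolved) {
  n <- length(segIds)
  switch(spec$kind,
         uniform = rep(spec$baseline, n),
         marker = {
           bad <- setdiff(spec$segments, segIds)
           if (length(bad))
             .segStop("badPattern",
                      sprintf("marker pattern references unknown segment(s): %s",
                              paste(bad, collapse = ", ")))
           v <- rep(spec$baseline, n)
           v[segIds %in% spec$segments] <- spec$baseline + spec$amplitude
           v
         },
         gradient = spec$baseline + spec$amplitude * (seq_len(n) - 1) / max(1, n - 1),
         copy_of = {
           if (!spec$source %in% names(resolved))
             .segStop("badPattern",
                      sprintf("copy_of references unknown planted gene '%s'",
                              spec$source))
           spec$scale * resolved[[spec$source]] + spec$offset
         },
         group_template = {
           bad <- setdiff(c(spec$groupA, spec$groupB), segIds)
           if (length(bad))
             .segStop("badPattern",
                      sprintf("group_template references unknown segment(s): %s",
                              paste(bad, collapse = ", ")))
           v <- rep(spec$baseline, n)
           v[segIds %in% spec$groupA] <- spec$baseline + spec$amplitude
           v
         },
         .segStop("badPattern", sprintf("unknown pattern kind '%s'", spec$kind)))
}

#' Generate a synthetic expression matrix with planted patterns
#'
#' Emulates the shape of a segment-resolved bulk RNA-seq atlas — genes by
#' segments, log2 CPM scale — at desk scale. Planted genes follow their
#' [patternSpecs] plus i.i.d. Gaussian cell noise `N(0, noiseSd^2)`; the
#' remaining background genes are independent `N(baseline, 1)` — spatially
#' unstructured expression. Generation is deterministic given `seed`
#' (Mersenne-Twister with inversion sampling, so seeds are portable across
#' platforms). Segment IDs are `S1...Sn`, matching
#' [makeSegmentedBlockMesh()]; background gene IDs are `G0001...`.
#'
#' @param nGenes Total number of genes (>= number of patterns; default 500).
#' @param nSegments Number of segments (>= 3; default 18, the atlas
#'   segmentation).
#' @param patterns Named list of `PatternSpec`s; names become planted gene
#'   IDs (unnamed entries get `P1`, `P2`, ...).
#' @param noiseSd Standard deviation of the per-cell noise on planted genes
#'   (default 0.5).
#' @param seed Integer RNG seed; `NULL` uses the current RNG state.
#' @return List with `matrix` (a [SegmentExperiment]) and `truth` (a
#'   data.frame describing each planted gene: `gene`, `kind`, `detail`,
#'   `partner` — the expected top association, if the pattern implies one).
#' @examples
#' sim <- makeSyntheticExpression(
#'   nGenes = 50, nSegments = 18,
#'   patterns = list(Qry = markerPattern(c("S1", "S2")),
#'                   Cpy = copyOfPattern("Qry", scale = 2, offset = 1)),
#'   noiseSd = 0, seed = 1)
#' similarityRecords(similarGenes(sim$matrix, "Qry", k = 1))
#' @export
makeSyntheticExpression <- function(nGenes = 500L, nSegments = 18L,
                                    patterns = list(), noiseSd = 0.5,
                                    seed = NULL) {
  nGenes <- as.integer(nGenes)
  nSegments <- as.integer(nSegments)
  if (nSegments < 3L)
    .segStop("badArgument", "'nSegments' must be at least 3")
  if (nGenes < length(patterns))
    .segStop("badArgument", "'nGenes' must be >= number of planted patterns")
  if (!is.numeric(noiseSd) || noiseSd < 0)
    .segStop("badArgument", "'noiseSd' must be non-negative")
  if (!is.null(seed))
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion")
  segIds <- paste0("S", seq_len(nSegments))
  pnames <- names(patterns)
  if (is.null(pnames)) pnames <- rep("", length(patterns))
  auto <- which(!nzchar(pnames))
  pnames[auto] <- paste0("P", seq_along(auto))
  if (anyDuplicated(pnames))
    .segStop("badPattern", "planted gene names must be unique")
  # resolve noiseless pattern values (copy_of may reference earlier patterns)
  resolved <- list()
  for (i in seq_along(patterns)) {
    if (!inherits(patterns[[i]], "PatternSpec"))
      .segStop("badPattern", "each pattern must be built with a pattern constructor")
    resolved[[pnames[i]]] <- .patternValues(patterns[[i]], segIds, resolved)
  }
  nBackground <- nGenes - length(patterns)
  bg <- if (nBackground > 0)
    matrix(rnorm(nBackground * nSegments, mean = 4, sd = 1),
           nBackground, nSegments)
  else matrix(numeric(), 0L, nSegments)
  planted <- if (length(patterns))
    do.call(rbind, lapply(pnames, function(g)
      resolved[[g]] + rnorm(nSegments, 0, noiseSd)))
  else matrix(numeric(), 0L, nSegments)
  vals <- rbind(planted, bg)
  rownames(vals) <- c(pnames,
                      if (nBackground > 0) sprintf("G%04d", seq_len(nBackground)))
  colnames(vals) <- segIds
  truth <- data.frame(
    gene = pnames,
    kind = vapply(patterns, `[[`, character(1), "kind"),
    detail = vapply(patterns, function(p) switch(
      p$kind,
      uniform = sprintf("baseline=%g", p$baseline),
      marker = paste(p$segments, collapse = ";"),
      gradient = sprintf("amplitude=%g", p$amplitude),
      copy_of = sprintf("%g*%s+%g", p$scale, p$source, p$offset),
      group_template = sprintf("A=%s|B=%s", paste(p$groupA, collapse = ";"),
                               paste(p$groupB, collapse = ";"))), character(1)),
    partner = vapply(patterns, function(p)
      if (p$kind == "copy_of") p$source else "", character(1)),
    stringsAsFactors = FALSE)
  list(matrix = SegmentExperiment(vals), truth = truth)
}

# 12 triangles of a unit cube with corner at `origin`
.cubeMesh <- function(origin) {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(v) <- NULL
  v <- v + matrix(origin, 8L, 3L, byrow = TRUE)
  # faces as 1-based indices into the 8 expand.grid corners
  f <- rbind(c(1, 3, 7), c(1, 7, 5),   # y = 0... (z faces etc.)
             c(2, 8, 4), c(2, 6, 8),
             c(1, 5, 6), c(1, 6, 2),
             c(3, 4, 8), c(3, 8, 7),
             c(1, 2, 4), c(1, 4, 3),
             c(5, 7, 8), c(5, 8, 6))
  list(vertices = v, faces = f)
}

#' Generate a synthetic segmented block mesh
#'
#' A stand-in for a dissected organ model: `nSegments` unit cubes laid out
#' row-major on a `rows x cols` grid in the x-z plane (y-up), named
#' `S1...Sn` in canonical order, each with 8 vertices and 12 triangles.
#' Neighbouring cubes are spaced 1.5 units apart, so the segmentation is
#' visible. Because the segment IDs match [makeSyntheticExpression()],
#' synthetic matrices map straight onto this mesh.
#'
#' @param nSegments Number of segments (default 18).
#' @param grid Integer `c(rows, cols)` with `rows * cols >= nSegments`
#'   (default `c(3, 6)`).
#' @return A [SegmentedModel].
#' @examples
#' makeSegmentedBlockMesh(18, c(3, 6))
#' @export
makeSegmentedBlockMesh <- function(nSegments = 18L, grid = c(3L, 6L)) {
  nSegments <- as.integer(nSegments)
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 1L))
    .segStop("badArgument", "'grid' must be c(rows, cols)")
  if (prod(grid) < nSegments)
    .segStop("gridTooSmall",
             sprintf("grid %d x %d cannot hold %d segments", grid[1], grid[2],
                     nSegments))
  meshes <- vector("list", nSegments)
  for (i in seq_len(nSegments)) {
    row <- (i - 1L) %/% grid[2L]
    col <- (i - 1L) %% grid[2L]
    meshes[[i]] <- .cubeMesh(c(1.5 * col, 0, 1.5 * row))
  }
  SegmentedModel(paste0("S", seq_len(nSegments)), meshes)
}
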