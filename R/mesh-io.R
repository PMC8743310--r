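## Mesh I/O.
## Input: ASCII Wavefront OBJ with one named `o`/`g` block per segment;
## vertices belong to the block in which they appear, faces use global
## (file-wide) 1-based indices and must reference their own block's vertices.
## Output: OBJ (same dialect), OBJ+MTL with one material per segment, and
## binary little-endian PLY with per-vertex uchar RGB.

#' Load a segmented mesh from a Wavefront OBJ file
#'
#' Each named `o` (or `g`) block becomes one segment, in order of first
#' appearance — that order is the canonical model order used everywhere else.
#' Vertex lines belong to the enclosing block; face indices are file-global
#' and are remapped to per-segment local indices. Texture/normal references
#' (`f v/vt/vn`) are accepted and ignored; polygons with more than 3 vertices
#' are fan-triangulated.
#'
#' @param path Path to the OBJ file.
#' @return A [SegmentedModel].
#' @seealso [writeSegmentedMesh()], [exportColoredMesh()]
#' @export
loadSegmentedMesh <- function(path) {
  if (!file.exists(path))
    .segStop("fileNotFound", sprintf("file not found: %s", path), category = "io")
  lines <- readLines(path, warn = FALSE)
  segIds <- character()
  verts <- list()   # per segment: list of numeric triples
  faces <- list()   # per segment: list of integer triples (global indices)
  offsets <- integer()  # global index of last vertex before each segment
  cur <- 0L
  nGlobal <- 0L
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[[:space:]]+")[[1L]]
    key <- tok[1L]
    if (key %in% c("o", "g")) {
      nm <- if (length(tok) >= 2L) paste(tok[-1L], collapse = " ") else ""
      if (!nzchar(nm))
        .segStop("badMesh", "unnamed 'o'/'g' group in OBJ file")
      if (nm %in% segIds)
        .segStop("duplicateGroupName",
                 sprintf("duplicate segment group '%s' in OBJ file", nm))
      segIds <- c(segIds, nm)
      cur <- length(segIds)
      verts[[cur]] <- list()
      faces[[cur]] <- list()
      offsets[cur] <- nGlobal
    } else if (key == "v") {
      if (cur == 0L)
        .segStop("noGroups", "vertex before any named 'o'/'g' group")
      verts[[cur]][[length(verts[[cur]]) + 1L]] <- as.numeric(tok[2:4])
      nGlobal <- nGlobal + 1L
    } else if (key == "f") {
      if (cur == 0L)
        .segStop("noGroups", "face before any named 'o'/'g' group")
      idx <- as.integer(vapply(strsplit(tok[-1L], "/", fixed = TRUE),
                               `[[`, character(1), 1L))
      if (any(is.na(idx)) || length(idx) < 3L)
        .segStop("badMesh", sprintf("unparseable face line: '%s'", ln))
      # fan-triangulate polygons
      for (j in seq_len(length(idx) - 2L))
        faces[[cur]][[length(faces[[cur]]) + 1L]] <-
          c(idx[1L], idx[j + 1L], idx[j + 2L])
    }
    # vt/vn/usemtl/mtllib/s lines are ignored
  }
  if (length(segIds) == 0L)
    .segStop("noGroups", "OBJ file contains no named 'o'/'g' groups")
  meshes <- vector("list", length(segIds))
  for (i in seq_along(segIds)) {
    nv <- length(verts[[i]])
    if (length(faces[[i]]) == 0L)
      .segStop("degenerateSegment",
               sprintf("segment '%s' has no faces", segIds[i]))
    f <- do.call(rbind, faces[[i]]) - offsets[i]
    if (nv == 0L || min(f) < 1L || max(f) > nv)
      .segStop("badMesh",
               sprintf("segment '%s': faces reference vertices outside the segment",
                       segIds[i]))
    v <- do.call(rbind, verts[[i]])
    meshes[[i]] <- list(vertices = v, faces = f)
  }
  SegmentedModel(segIds, meshes)
}

#' Write a segmented mesh to a Wavefront OBJ file
#'
#' Inverse of [loadSegmentedMesh()]: one `o` block per segment in canonical
#' order, global vertex indexing, coordinates at full double precision.
#'
#' @param model A [SegmentedModel].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeSegmentedMesh <- function(model, path) {
  stopifnot(is(model, "SegmentedModel"))
  out <- character()
  off <- 0L
  for (i in seq_along(model@segmentIds)) {
    mesh <- model@meshes[[i]]
    out <- c(out, paste("o", model@segmentIds[i]),
             sprintf("v %.17g %.17g %.17g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]),
             sprintf("f %d %d %d",
                     mesh$faces[, 1] + off, mesh$faces[, 2] + off,
                     mesh$faces[, 3] + off))
    off <- off + nrow(mesh$vertices)
  }
  writeLines(out, path)
  invisible(path)
}

#' Attach per-segment colors to a mesh
#'
#' Assigns each segment's color (from a [SegmentColorMap], e.g. the output of
#' [geneToSegmentColors()]) uniformly to all of that segment's vertices. The
#' color map's segment IDs must match the model's as a set; colors are looked
#' up by ID, so the two objects need not share an order.
#'
#' @param model A [SegmentedModel].
#' @param colorMap A [SegmentColorMap].
#' @return A [ColoredModel].
#' @export
applySegmentColors <- function(model, colorMap) {
  stopifnot(is(model, "SegmentedModel"), is(colorMap, "SegmentColorMap"))
  if (!setequal(segmentIds(model), segmentIds(colorMap)))
    .segStop("segmentMismatch",
             sprintf("model segments do not match color map segments (%d vs %d; %s)",
                     nSegments(model), nSegments(colorMap),
                     paste(head(c(setdiff(segmentIds(model), segmentIds(colorMap)),
                                  setdiff(segmentIds(colorMap), segmentIds(model))), 3),
                           collapse = ", ")))
  new("ColoredModel", model = model, colorMap = colorMap)
}

# colors of a ColoredModel in model segment order
.modelOrderColors <- function(cm) {
  cols <- segmentColors(cm@colorMap)
  cols[segmentIds(cm@model), , drop = FALSE]
}

#' Export a colored mesh to PLY or OBJ+MTL
#'
#' `"ply"` writes a binary little-endian PLY with per-vertex 8-bit RGB (the
#' widest-supported vertex-color interchange format). `"obj"` writes an OBJ
#' plus a sidecar `.mtl` with one diffuse material per segment. Both preserve
#' segment vertex/face counts and 8-bit colors exactly.
#'
#' @param colored A [ColoredModel].
#' @param path Output file path (for `"obj"`, the `.mtl` is written next to
#'   it).
#' @param format `"ply"` or `"obj"`.
#' @return The path, invisibly.
#' @seealso [readPLY()] for reading the PLY back.
#' @export
exportColoredMesh <- function(colored, path, format = c("ply", "obj")) {
  stopifnot(is(colored, "ColoredModel"))
  if (length(format) == 1L && !format %in% c("ply", "obj"))
    .segStop("unsupportedFormat",
             sprintf("unsupported mesh export format '%s'", format))
  format <- match.arg(format)
  if (format == "ply") .writePLY(colored, path) else .writeOBJMTL(colored, path)
  invisible(path)
}

.writePLY <- function(colored, path) {
  model <- colored@model
  cols <- .modelOrderColors(colored)
  vlist <- lapply(model@meshes, `[[`, "vertices")
  nv <- vapply(vlist, nrow, integer(1))
  V <- do.call(rbind, vlist)
  C <- do.call(rbind, lapply(seq_along(nv), function(i)
    matrix(cols[i, ], nv[i], 3L, byrow = TRUE)))
  off <- cumsum(c(0L, nv[-length(nv)]))
  F <- do.call(rbind, lapply(seq_along(nv), function(i)
    colored@model@meshes[[i]]$faces + off[i]))
  header <- paste0(
    "ply\nformat binary_little_endian 1.0\n",
    "comment segatlas colored mesh\n",
    sprintf("element vertex %d\n", nrow(V)),
    "property float x\nproperty float y\nproperty float z\n",
    "property uchar red\nproperty uchar green\nproperty uchar blue\n",
    sprintf("element face %d\n", nrow(F)),
    "property list uchar int vertex_indices\nend_header\n")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  # interleave 12 float bytes + 3 color bytes per vertex
  fb <- writeBin(as.numeric(t(V)), raw(), size = 4L, endian = "little")
  vb <- matrix(as.raw(0), 15L, nrow(V))
  vb[1:12, ] <- matrix(fb, 12L, nrow(V))
  vb[13:15, ] <- matrix(as.raw(t(C)), 3L, nrow(V))
  writeBin(as.vector(vb), con)
  # faces: uchar count (3) + 3 int32 (0-based)
  ib <- writeBin(as.integer(t(F) - 1L), raw(), size = 4L, endian = "little")
  fbm <- matrix(as.raw(0), 13L, nrow(F))
  fbm[1L, ] <- as.raw(3L)
  fbm[2:13, ] <- matrix(ib, 12L, nrow(F))
  writeBin(as.vector(fbm), con)
  invisible(path)
}

#' Read a binary little-endian PLY file with per-vertex colors
#'
#' Reads the PLY dialect written by [exportColoredMesh()]: float32 xyz plus
#' uchar RGB per vertex, int32 triangle indices. Mainly for round-trip
#' verification of exports.
#'
#' @param path Path to the PLY file.
#' @return List with `vertices` (n x 3), `colors` (n x 3 integer, 0-255),
#'   `faces` (m x 3, 1-based).
#' @export
readPLY <- function(path) {
  if (!file.exists(path))
    .segStop("fileNotFound", sprintf("file not found: %s", path), category = "io")
  raw <- readBin(path, "raw", n = file.size(path))
  marker <- charToRaw("end_header\n")
  hdrEnd <- 0L
  for (i in seq_len(length(raw) - length(marker) + 1L)) {
    if (all(raw[i:(i + length(marker) - 1L)] == marker)) {
      hdrEnd <- i + length(marker) - 1L
      break
    }
  }
  if (hdrEnd == 0L)
    .segStop("badMesh", "not a PLY file (no end_header)")
  hdr <- strsplit(rawToChar(raw[1:hdrEnd]), "\n", fixed = TRUE)[[1L]]
  if (hdr[1L] != "ply" || !any(grepl("binary_little_endian", hdr)))
    .segStop("badMesh", "expected a binary little-endian PLY")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", hdr, value = TRUE)))
  body <- raw[(hdrEnd + 1L):length(raw)]
  vb <- matrix(body[seq_len(15L * nv)], 15L, nv)
  V <- matrix(readBin(as.vector(vb[1:12, ]), "numeric", n = 3L * nv, size = 4L,
                      endian = "little"), ncol = 3L, byrow = TRUE)
  C <- matrix(as.integer(as.vector(vb[13:15, ])), ncol = 3L, byrow = TRUE)
  fb <- matrix(body[15L * nv + seq_len(13L * nf)], 13L, nf)
  F <- matrix(readBin(as.vector(fb[2:13, ]), "integer", n = 3L * nf, size = 4L,
                      endian = "little"), ncol = 3L, byrow = TRUE) + 1L
  list(vertices = V, colors = C, faces = F)
}

.writeOBJMTL <- function(colored, path) {
  model <- colored@model
  cols <- .modelOrderColors(colored)
  mtlPath <- sub("\\.obj$", ".mtl", path)
  if (identical(mtlPath, path)) mtlPath <- paste0(path, ".mtl")
  mtl <- character()
  out <- paste("mtllib", basename(mtlPath))
  off <- 0L
  for (i in seq_along(model@segmentIds)) {
    sid <- model@segmentIds[i]
    mesh <- model@meshes[[i]]
    mtl <- c(mtl, sprintf("newmtl seg_%s", sid),
             sprintf("Kd %.6f %.6f %.6f", cols[i, 1] / 255, cols[i, 2] / 255,
                     cols[i, 3] / 255), "")
    out <- c(out, paste("o", sid), sprintf("usemtl seg_%s", sid),
             sprintf("v %.17g %.17g %.17g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]),
             sprintf("f %d %d %d", mesh$faces[, 1] + off, mesh$faces[, 2] + off,
                     mesh$faces[, 3] + off))
    off <- off + nrow(mesh$vertices)
  }
  writeLines(out, path)
  writeLines(mtl, mtlPath)
  invisible(path)
}
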