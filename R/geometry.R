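## Rigid whole-model transforms and the exploded ("expanded") layout.

#' Rotation matrix about a coordinate axis
#'
#' Convenience constructor for proper rotations used with
#' [transformModel()].
#'
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param angleDeg Rotation angle in degrees (right-handed).
#' @return A 3 x 3 rotation matrix.
#' @examples
#' rotationMatrix("z", 90)
#' @export
rotationMatrix <- function(axis = c("x", "y", "z"), angleDeg) {
  axis <- match.arg(axis)
  a <- angleDeg * pi / 180
  c_ <- cos(a); s_ <- sin(a)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, -s_, 0, s_, c_), 3, 3, byrow = TRUE),
         y = matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, 3, byrow = TRUE),
         z = matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE))
}

.checkRotation <- function(R) {
  if (!is.matrix(R) || !identical(dim(R), c(3L, 3L)) || any(!is.finite(R)))
    .segStop("improperRotation", "rotation must be a finite 3 x 3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-9)
    .segStop("improperRotation",
             "rotation must be orthogonal with determinant +1 (within 1e-9)")
  invisible(R)
}

#' Rigidly transform a whole segmented model
#'
#' Applies one rotation followed by one translation to every segment jointly
#' (the headless equivalent of grabbing the whole-model handle): each vertex
#' becomes `R v + t`. Being rigid, the transform preserves all pairwise
#' vertex distances.
#'
#' @param model A [SegmentedModel].
#' @param rotation 3 x 3 proper rotation matrix (orthogonal, det +1 within
#'   1e-9). Default: identity.
#' @param translation Numeric length-3 translation vector. Default: zero.
#' @return The transformed [SegmentedModel].
#' @export
transformModel <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is(model, "SegmentedModel"))
  .checkRotation(rotation)
  if (length(translation) != 3L || any(!is.finite(translation)))
    .segStop("badArgument", "'translation' must be a finite length-3 vector")
  meshes <- lapply(model@meshes, function(mesh) {
    mesh$vertices <- mesh$vertices %*% t(rotation) +
      matrix(translation, nrow(mesh$vertices), 3L, byrow = TRUE)
    mesh
  })
  new("SegmentedModel", segmentIds = model@segmentIds, meshes = meshes)
}

# mean bounding-box extent of segments along a unit axis
.meanExtentAlong <- function(model, axis) {
  mean(vapply(model@meshes, function(mesh) {
    p <- as.numeric(mesh$vertices %*% axis)
    max(p) - min(p)
  }, numeric(1)))
}

#' Exploded ("expanded") layout of a segmented model
#'
#' Translates segment `i` (1-based, canonical order) rigidly by
#' `(i - 1) * spacing` along `axis`, spreading the segments out in a row so
#' interior segments become visible while each segment's geometry is
#' unchanged. The default spacing is 1.2 times the mean segment bounding-box
#' extent along the axis, leaving a visible gap between neighbouring
#' segments. Reapplying with `-spacing`... i.e. translating each segment back
#' by the same offsets restores the original coordinates exactly.
#'
#' @param model A [SegmentedModel].
#' @param axis Length-3 direction vector (normalized internally; default x).
#' @param spacing Positive distance between consecutive segment offsets;
#'   `NULL` for the default.
#' @return The laid-out [SegmentedModel].
#' @export
explodeLayout <- function(model, axis = c(1, 0, 0), spacing = NULL) {
  stopifnot(is(model, "SegmentedModel"))
  if (length(axis) != 3L || any(!is.finite(axis)) || sum(axis^2) == 0)
    .segStop("badArgument", "'axis' must be a non-zero length-3 vector")
  axis <- axis / sqrt(sum(axis^2))
  if (is.null(spacing)) spacing <- 1.2 * .meanExtentAlong(model, axis)
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    .segStop("zeroSpacing", "'spacing' must be a positive number")
  meshes <- model@meshes
  for (i in seq_along(meshes)) {
    off <- (i - 1) * spacing * axis
    meshes[[i]]$vertices <- meshes[[i]]$vertices +
      matrix(off, nrow(meshes[[i]]$vertices), 3L, byrow = TRUE)
  }
  new("SegmentedModel", segmentIds = model@segmentIds, meshes = meshes)
}
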