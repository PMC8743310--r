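## Deterministic offscreen snapshot rendering.
## A small software rasterizer (perspective camera, z-buffer, flat per-segment
## shading) so snapshots are bit-reproducible and need no GPU or display.

# Rasterize triangles into an RGB array. V2: n x 2 pixel coords, Z: n depth
# values (camera distance), F: m x 3 indices, colM: m x 3 colors in [0,1].
.rasterize <- function(V2, Z, F, colM, size, background = c(1, 1, 1)) {
  img <- array(rep(background, each = size * size), dim = c(size, size, 3L))
  zbuf <- matrix(Inf, size, size)
  for (k in seq_len(nrow(F))) {
    i <- F[k, ]
    x <- V2[i, 1L]; y <- V2[i, 2L]; z <- Z[i]
    xmin <- max(1L, floor(min(x))); xmax <- min(size, ceiling(max(x)))
    ymin <- max(1L, floor(min(y))); ymax <- min(size, ceiling(max(y)))
    if (xmin > xmax || ymin > ymax) next
    denom <- (y[2] - y[3]) * (x[1] - x[3]) + (x[3] - x[2]) * (y[1] - y[3])
    if (abs(denom) < 1e-12) next
    cols <- rep(xmin:xmax, times = ymax - ymin + 1L)   # 1-based pixel column
    rows <- rep(ymin:ymax, each = xmax - xmin + 1L)    # 1-based pixel row
    px <- cols - 0.5                                   # pixel centers
    py <- rows - 0.5
    w1 <- ((y[2] - y[3]) * (px - x[3]) + (x[3] - x[2]) * (py - y[3])) / denom
    w2 <- ((y[3] - y[1]) * (px - x[3]) + (x[1] - x[3]) * (py - y[3])) / denom
    w3 <- 1 - w1 - w2
    inside <- w1 >= -1e-9 & w2 >= -1e-9 & w3 >= -1e-9
    if (!any(inside)) next
    zi <- w1 * z[1] + w2 * z[2] + w3 * z[3]
    sel <- which(inside)
    # column-major linear index into the size x size image plane
    lin <- rows[sel] + (cols[sel] - 1L) * size
    closer <- zi[sel] < zbuf[lin]
    if (!any(closer)) next
    lin <- lin[closer]
    zbuf[lin] <- zi[sel][closer]
    img[lin] <- colM[k, 1L]
    img[lin + size * size] <- colM[k, 2L]
    img[lin + 2L * size * size] <- colM[k, 3L]
  }
  img
}

# project model vertices for a camera at yaw (degrees) orbiting `center` at
# distance `dist`, elevation 0, y-up, 60 degree vertical FOV
.projectForYaw <- function(V, center, dist, yawDeg, size, fovDeg = 60) {
  yaw <- yawDeg * pi / 180
  dir <- c(sin(yaw), 0, cos(yaw))
  eye <- center + dist * dir
  f <- -dir                                  # forward: eye -> center
  up <- c(0, 1, 0)
  r <- c(f[3] * up[2] - f[2] * up[3],        # right = f x up
         f[1] * up[3] - f[3] * up[1],
         f[2] * up[1] - f[1] * up[2])
  r <- r / sqrt(sum(r^2))
  u <- c(r[2] * f[3] - r[3] * f[2],          # true up = r x f
         r[3] * f[1] - r[1] * f[3],
         r[1] * f[2] - r[2] * f[1])
  P <- sweep(V, 2L, eye)
  xc <- as.numeric(P %*% r)
  yc <- as.numeric(P %*% u)
  zc <- as.numeric(P %*% f)                  # positive in front of camera
  tanH <- tan(fovDeg / 2 * pi / 180)
  xn <- (xc / zc) / tanH
  yn <- (yc / zc) / tanH
  cbind((xn + 1) / 2 * size, (1 - (yn + 1) / 2) * size, zc)
}

#' Render multi-angle snapshots of a colored model
#'
#' Renders `nAngles` PNG images of the colored model with a perspective
#' camera orbiting the model centroid at equally spaced yaw angles
#' (360/nAngles degrees apart, starting at 0), elevation 0, 60-degree
#' vertical field of view, framed so the whole bounding sphere is visible.
#' Only the model is drawn (white background, flat per-segment colors, no
#' auxiliary scene content), and rendering is fully deterministic: two calls
#' with the same model and parameters produce pixel-identical files. Files
#' are named `snap_<yaw>.png` with the yaw zero-padded to three digits
#' (`snap_000.png` ... `snap_270.png` for the default four angles).
#'
#' @param colored A [ColoredModel].
#' @param outDir Output directory (created if missing).
#' @param nAngles Number of evenly spaced yaw angles (default 4).
#' @param imageSize Image width/height in pixels (default 1024).
#' @return Character vector of the PNG paths, in yaw order.
#' @export
renderSnapshots <- function(colored, outDir, nAngles = 4L, imageSize = 1024L) {
  stopifnot(is(colored, "ColoredModel"))
  if (!is.numeric(nAngles) || length(nAngles) != 1L || nAngles < 1)
    .segStop("badArgument", "'nAngles' must be a positive integer")
  nAngles <- as.integer(nAngles)
  imageSize <- as.integer(imageSize)
  model <- colored@model
  if (nSegments(model) == 0L)
    .segStop("emptyModel", "cannot render an empty model")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  cols <- .modelOrderColors(colored) / 255
  nv <- vapply(model@meshes, function(m) nrow(m$vertices), integer(1))
  nf <- vapply(model@meshes, function(m) nrow(m$faces), integer(1))
  off <- cumsum(c(0L, nv[-length(nv)]))
  V <- do.call(rbind, lapply(model@meshes, `[[`, "vertices"))
  F <- do.call(rbind, lapply(seq_along(nv), function(i)
    model@meshes[[i]]$faces + off[i]))
  colM <- do.call(rbind, lapply(seq_along(nf), function(i)
    matrix(cols[i, ], nf[i], 3L, byrow = TRUE)))
  center <- colMeans(V)
  radius <- sqrt(max(rowSums(sweep(V, 2L, center)^2)))
  if (radius == 0) radius <- 1
  dist <- radius / sin(30 * pi / 180) * 1.1   # fit bounding sphere, 10% margin
  yaws <- 360 * (seq_len(nAngles) - 1L) / nAngles
  paths <- character(nAngles)
  for (i in seq_len(nAngles)) {
    proj <- .projectForYaw(V, center, dist, yaws[i], imageSize)
    img <- .rasterize(proj[, 1:2, drop = FALSE], proj[, 3], F, colM, imageSize)
    paths[i] <- file.path(outDir, sprintf("snap_%03d.png", as.integer(round(yaws[i]))))
    png::writePNG(img, paths[i])
  }
  paths
}
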