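# Segmented mesh I/O, rigid transforms, exploded layout, colored export.

test_that("OBJ loader parses named segment blocks in file order", {
  obj <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("# two triangles in two segments",
               "o base", "v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3",
               "o apex", "v 0 0 1", "v 1 0 1", "v 0 1 1", "f 4/1/1 5/2/2 6/3/3"),
             obj)
  model <- loadSegmentedMesh(obj)
  expect_identical(segmentIds(model), c("base", "apex"))
  meshes <- segmentMeshes(model)
  expect_identical(unname(meshes$apex$faces), matrix(c(1L, 2L, 3L), 1))
  expect_equal(meshes$apex$vertices[, 3], c(1, 1, 1))

  writeLines(c("o a", "v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3",
               "o a", "v 0 0 1", "v 1 0 1", "v 0 1 1", "f 4 5 6"), obj)
  expect_segatlas_error(loadSegmentedMesh(obj), "duplicateGroupName")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), obj)
  expect_segatlas_error(loadSegmentedMesh(obj), "noGroups")
  writeLines(c("o a", "v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3", "o b",
               "v 0 0 1"), obj)
  expect_segatlas_error(loadSegmentedMesh(obj), "degenerateSegment")
})

test_that("segmented mesh OBJ write/load round trip is faithful", {
  model <- makeSegmentedBlockMesh(18, c(3, 6))
  path <- withr::local_tempfile(fileext = ".obj")
  writeSegmentedMesh(model, path)
  back <- loadSegmentedMesh(path)
  expect_identical(segmentIds(back), segmentIds(model))
  for (s in segmentIds(model)) {
    expect_equal(segmentMeshes(back)[[s]]$vertices,
                 segmentMeshes(model)[[s]]$vertices)
    expect_identical(segmentMeshes(back)[[s]]$faces,
                     segmentMeshes(model)[[s]]$faces)
  }
})

test_that("rigid transforms preserve distances and compose as a group", {
  model <- makeSegmentedBlockMesh(6, c(2, 3))
  d0 <- allPairDistances(model)
  R <- rotationMatrix("z", 33.3)
  t <- c(1.5, -2, 0.25)
  moved <- transformModel(model, R, t)
  expect_lt(max(abs(allPairDistances(moved) - d0)), 1e-9)
  # identity transform leaves the model untouched
  ident <- transformModel(model)
  expect_equal(segmentMeshes(ident), segmentMeshes(model))
  # 90 degrees about z twice == 180 once
  twice <- transformModel(transformModel(model, rotationMatrix("z", 90)),
                          rotationMatrix("z", 90))
  once <- transformModel(model, rotationMatrix("z", 180))
  for (s in segmentIds(model))
    expect_lt(max(abs(segmentMeshes(twice)[[s]]$vertices -
                        segmentMeshes(once)[[s]]$vertices)), 1e-9)
  # centroid-to-centroid distances are preserved too
  cent <- function(m) t(vapply(segmentMeshes(m),
                               function(x) colMeans(x$vertices), numeric(3)))
  expect_lt(max(abs(dist(cent(moved)) - dist(cent(model)))), 1e-9)
  expect_segatlas_error(transformModel(model, diag(3) * 2), "improperRotation")
  reflect <- diag(c(-1, 1, 1))  # orthogonal but det -1
  expect_segatlas_error(transformModel(model, reflect), "improperRotation")
})

test_that("exploded layout offsets segments by index along the axis", {
  model <- makeSegmentedBlockMesh(3, c(1, 3))
  ex <- explodeLayout(model, axis = c(1, 0, 0), spacing = 2)
  for (i in 1:3) {
    shift <- segmentMeshes(ex)[[i]]$vertices - segmentMeshes(model)[[i]]$vertices
    expect_equal(unique(shift[, 1]), (i - 1) * 2)   # +0, +2, +4
    expect_true(all(shift[, 2:3] == 0))             # rigid: pure translation
  }
  # collapse: exploding back along the opposite axis restores coordinates
  restored <- explodeLayout(ex, axis = c(-1, 0, 0), spacing = 2)
  for (i in 1:3)
    expect_identical(segmentMeshes(restored)[[i]]$vertices,
                     segmentMeshes(model)[[i]]$vertices)
  single <- makeSegmentedBlockMesh(1, c(1, 1))
  expect_equal(segmentMeshes(explodeLayout(single, spacing = 3)),
               segmentMeshes(single))  # first segment has zero offset
  expect_segatlas_error(explodeLayout(model, spacing = 0), "zeroSpacing")
  expect_segatlas_error(explodeLayout(model, axis = c(0, 0, 0)), "badArgument")
  # default spacing scales with segment extent and leaves gaps
  ex2 <- explodeLayout(model)
  s2 <- segmentMeshes(ex2)[[2]]$vertices - segmentMeshes(model)[[2]]$vertices
  expect_equal(unique(s2[, 1]), 1.2)  # unit cubes: 1.2 x mean extent
})

test_that("per-segment colors attach by ID and export round trips", {
  model <- makeSegmentedBlockMesh(4, c(2, 2))
  sim <- makeSyntheticExpression(nGenes = 5, nSegments = 4,
                                 patterns = list(g = gradientPattern()),
                                 noiseSd = 0, seed = 1)
  cm <- geneToSegmentColors(sim$matrix, "g")
  colored <- applySegmentColors(model, cm)
  expect_s4_class(colored, "ColoredModel")
  short <- makeSegmentedBlockMesh(3, c(1, 3))
  expect_segatlas_error(applySegmentColors(short, cm), "segmentMismatch")

  ply <- withr::local_tempfile(fileext = ".ply")
  exportColoredMesh(colored, ply)
  back <- readPLY(ply)
  expect_identical(nrow(back$vertices), 32L)   # 4 cubes x 8 vertices
  expect_identical(nrow(back$faces), 48L)      # 4 cubes x 12 triangles
  V <- do.call(rbind, lapply(segmentMeshes(model), `[[`, "vertices"))
  expect_equal(back$vertices, V, tolerance = 1e-6)  # float32 precision
  wanted <- segmentColors(cm)[segmentIds(model), ]
  expect_identical(back$colors,
                   wanted[rep(1:4, each = 8), , drop = FALSE],
                   ignore_attr = TRUE)  # colors bit-exact per segment

  objp <- withr::local_tempfile(fileext = ".obj")
  exportColoredMesh(colored, objp, format = "obj")
  mtl <- readLines(sub("\\.obj$", ".mtl", objp))
  expect_identical(sum(grepl("^newmtl ", mtl)), 4L)  # one material per segment
  expect_segatlas_error(exportColoredMesh(colored, ply, format = "stl"),
                        "unsupportedFormat")
})

test_that("PLY colors survive the round trip bit-exactly", {
  model <- makeSegmentedBlockMesh(2, c(1, 2))
  cm <- new("SegmentColorMap", segmentIds = c("S1", "S2"),
            colors = rbind(c(0L, 0L, 255L), c(255L, 0L, 0L)),
            sourceGene = "x", mode = "normalized",
            palette = segPalette("default"))
  ply <- withr::local_tempfile(fileext = ".ply")
  exportColoredMesh(applySegmentColors(model, cm), ply)
  back <- readPLY(ply)
  expect_identical(back$colors[1:8, ],
                   matrix(rep(c(0L, 0L, 255L), each = 8), 8))
  expect_identical(back$colors[9:16, ],
                   matrix(rep(c(255L, 0L, 0L), each = 8), 8))
})

test_that("snapshots: four deterministic angles framing the model", {
  sim <- makeSyntheticExpression(nGenes = 3, nSegments = 18,
                                 patterns = list(g = gradientPattern()),
                                 noiseSd = 0, seed = 2)
  colored <- applySegmentColors(makeSegmentedBlockMesh(),
                                geneToSegmentColors(sim$matrix, "g"))
  dir1 <- withr::local_tempdir()
  paths <- renderSnapshots(colored, dir1, nAngles = 4, imageSize = 64)
  expect_identical(basename(paths),
                   c("snap_000.png", "snap_090.png", "snap_180.png",
                     "snap_270.png"))
  expect_true(all(file.exists(paths)))
  imgs <- lapply(paths, png::readPNG)
  # the model is visible from every angle (not an all-background frame)
  for (img in imgs) expect_gt(sum(img != 1), 0)
  # two renders of the same scene are pixel-identical
  dir2 <- withr::local_tempdir()
  paths2 <- renderSnapshots(colored, dir2, nAngles = 4, imageSize = 64)
  for (i in 1:4)
    expect_identical(png::readPNG(paths[i]), png::readPNG(paths2[i]))
  one <- renderSnapshots(colored, withr::local_tempdir(), nAngles = 1,
                         imageSize = 32)
  expect_identical(basename(one), "snap_000.png")
  expect_segatlas_error(renderSnapshots(colored, dir1, nAngles = 0),
                        "badArgument")
})
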