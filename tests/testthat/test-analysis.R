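# Synexpression ranking, heatmap differences, and group contrasts.

test_that("similarityScore is |Pearson r| as a percentage", {
  expect_equal(similarityScore(c(1, 2, 3), c(2, 4, 6)), 100)
  expect_equal(similarityScore(c(1, 2, 3), c(3, 2, 1)), 100)  # anti-correlated
  expect_equal(similarityScore(c(1, 2, 3, 4), c(1, 3, 2, 4)), 80)
  expect_segatlas_error(similarityScore(c(1, 1, 1), c(1, 2, 3)), "zeroVariance")
  expect_segatlas_error(similarityScore(c(1, 2, 3), c(1, 2)), "badArgument")
  expect_segatlas_error(similarityScore(c(1, 2), c(3, 4)), "badArgument")
})

test_that("similarityScore is symmetric and affine-invariant", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(18); y <- rnorm(18)
    a <- runif(1, -4, 4); b <- rnorm(1)
    if (abs(a) < 0.1) a <- 0.5
    expect_equal(similarityScore(x, y), similarityScore(y, x))
    expect_equal(similarityScore(a * x + b, y), similarityScore(x, y),
                 tolerance = 1e-12)
    expect_equal(similarityScore(x, a * y + b), similarityScore(x, y),
                 tolerance = 1e-12)
    expect_equal(similarityScore(x, y),
                 100 * abs(bruteforcePearson(x, y)), tolerance = 1e-12)
  }
})

test_that("similarGenes matches a brute-force all-pairs oracle exactly", {
  se <- randomExpression(50, 18, seed = 77)
  tab <- similarGenes(se, "G001")
  oracle <- bruteforceRanking(
    exprValues(se)[setdiff(geneIds(se), "G001"), ], exprValues(se)["G001", ])
  rec <- similarityRecords(tab)
  expect_identical(rec$gene, oracle$gene)           # bit-for-bit order
  expect_equal(rec$similarity_percent, oracle$score, tolerance = 1e-12)
  expect_lt(max(rec$similarity_percent), 90)        # noise genes score low
})

test_that("similarGenes ranks planted affine copies first at exactly 100", {
  se <- randomExpression(30, 18, seed = 12)
  m <- exprValues(se)
  m <- rbind(m, twin = 2 * m["G001", ] + 7)
  se2 <- SegmentExperiment(m)
  rec <- similarityRecords(similarGenes(se2, "G001", k = 3))
  expect_identical(rec$gene[1], "twin")
  expect_equal(rec$similarity_percent[1], 100)
  # symmetric: the copy retrieves the original identically
  rec2 <- similarityRecords(similarGenes(se2, "twin", k = 3))
  expect_identical(rec2$gene[1], "G001")
  expect_equal(rec2$similarity_percent[1], 100)
})

test_that("similarGenes honours k, tie order, skipping and error contracts", {
  se <- randomExpression(101, 18, seed = 8)
  rec <- similarityRecords(similarGenes(se, "G001", k = 5))
  expect_identical(nrow(rec), 5L)
  expect_identical(rec$rank, 1:5)
  full <- similarityRecords(similarGenes(se, "G001"))
  expect_identical(nrow(full), 100L)
  expect_false("G001" %in% full$gene)  # query excluded from its own ranking
  s <- full$similarity_percent
  expect_true(all(diff(s) <= 0))
  # exact ties (duplicated rows) are ordered by gene ID
  m <- exprValues(tinyExpression())
  m <- rbind(m, zz_dup = m["down", ], aa_dup = m["down", ])
  tab <- similarityRecords(similarGenes(SegmentExperiment(m), "up"))
  expect_identical(tab$gene[1:3], c("aa_dup", "down", "zz_dup"))
  expect_equal(tab$similarity_percent[1:3], rep(100, 3))
  # constant genes are skipped and reported, not ranked
  st <- similarGenes(SegmentExperiment(m), "up")
  expect_identical(skippedGenes(st), "flat")
  expect_false("flat" %in% tab$gene)
  expect_segatlas_error(similarGenes(se, "missing"), "unknownGene")
  expect_segatlas_error(
    similarGenes(SegmentExperiment(m), "flat"), "queryZeroVariance")
})

test_that("heatmapDiff computes mode-dependent per-segment distances", {
  m <- matrix(c(1, 2, 0,
                2, 4, 0), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("S1", "S2", "S3")))
  se <- SegmentExperiment(m)
  # same shape at different magnitude: zero diff everywhere in normalized view
  hm <- heatmapDiff(se, "A", "B", "normalized")
  expect_equal(unname(heatmapDiffs(hm)), c(0, 0, 0))
  # absolute view keeps magnitudes: |1-2|, |2-4|, |0-0|
  hm2 <- heatmapDiff(se, "A", "B", "absolute")
  expect_equal(unname(heatmapDiffs(hm2)), c(1, 2, 0))
  cols <- segmentColors(heatmapColors(hm2))
  expect_identical(unname(cols["S2", ]), c(255L, 0L, 0L))  # largest diff: red
  expect_identical(unname(cols["S3", ]), c(0L, 0L, 255L))  # smallest: blue
})

test_that("heatmapDiff is symmetric, zero iff equal, mid-colored when flat", {
  se <- randomExpression(12, 18, seed = 4)
  ab <- heatmapDiff(se, "G001", "G002", "absolute")
  ba <- heatmapDiff(se, "G002", "G001", "absolute")
  expect_equal(heatmapDiffs(ab), heatmapDiffs(ba))
  expect_identical(segmentColors(heatmapColors(ab)),
                   segmentColors(heatmapColors(ba)))
  # self-comparison: identically zero, uniform mid color
  self <- heatmapDiff(se, "G001", "G001", "normalized")
  expect_true(all(heatmapDiffs(self) == 0))
  expect_identical(unique(unname(segmentColors(heatmapColors(self)))[, 1]), 128L)
  expect_true(all(heatmapDiffs(heatmapDiff(se, "G003", "G004", "absolute")) >= 0))
  expect_segatlas_error(heatmapDiff(se, "G001", "nope"), "unknownGene")
})

test_that("groupContrast ranks genes against the binary region template", {
  se <- randomExpression(40, 18, seed = 31)
  m <- exprValues(se)
  groupA <- paste0("S", 1:3)
  groupB <- paste0("S", 10:11)
  marker <- rep(4, 18); names(marker) <- segmentIds(se)
  marker[groupA] <- 10; marker[groupB] <- 0
  se2 <- SegmentExperiment(rbind(m, marker = marker))
  sel <- GroupSelection(groupA, groupB)
  rec <- similarityRecords(groupContrast(se2, sel))
  expect_identical(rec$gene[1], "marker")
  expect_equal(rec$similarity_percent[1], 100)
  # full ranking equals the brute-force template oracle
  template <- c(rep(1, 3), rep(0, 2))
  oracle <- bruteforceRanking(
    exprValues(se2)[, c(groupA, groupB)], template)
  oracle <- oracle[oracle$gene %in% rec$gene, ]
  expect_identical(rec$gene, oracle$gene)
  expect_equal(rec$similarity_percent, oracle$score, tolerance = 1e-12)
  # swapping the groups leaves scores unchanged (|r| is sign-invariant)
  swapped <- similarityRecords(groupContrast(se2, GroupSelection(groupB, groupA)))
  expect_identical(swapped$gene, rec$gene)
  expect_equal(swapped$similarity_percent, rec$similarity_percent)
})

test_that("groupContrast validates the selection and skips flat genes", {
  se <- randomExpression(10, 18, seed = 2)
  m <- exprValues(se)
  m <- rbind(m, flatsel = c(rep(1, 5), rnorm(13)))
  colnames(m) <- segmentIds(se)
  se2 <- SegmentExperiment(m)
  sel <- GroupSelection(paste0("S", 1:3), paste0("S", 4:5))
  st <- groupContrast(se2, sel)
  expect_identical(skippedGenes(st), "flatsel")  # constant over the selection
  expect_segatlas_error(GroupSelection(c("S1", "S2"), c("S2", "S3")),
                        "overlappingGroups")
  expect_segatlas_error(GroupSelection(character(), "S1"), "emptyGroup")
  expect_segatlas_error(
    groupContrast(se2, GroupSelection("S1", c("S2", "S99"))), "unknownSegment")
  # mean_diff secondary statistic: the planted marker still ranks first
  marker <- rep(0, 18); marker[1:3] <- 10; names(marker) <- segmentIds(se)
  se3 <- SegmentExperiment(rbind(m, marker = marker))
  md <- similarityRecords(groupContrast(se3, sel, method = "mean_diff"))
  expect_identical(md$gene[1], "marker")
  expect_equal(md$similarity_percent[1], 100)
})
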