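# Independent oracles and small fixture builders used across the suite.

# Pearson correlation from first principles (sums only), independent of
# stats::cor and of the package's ranking path.
bruteforcePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# brute-force all-rows ranking against a target vector: returns a data.frame
# ordered by descending |r|*100, ties by gene ID
bruteforceRanking <- function(m, target) {
  score <- vapply(rownames(m), function(g) {
    100 * abs(bruteforcePearson(m[g, ], target))
  }, numeric(1))
  df <- data.frame(gene = names(score), score = unname(score),
                   stringsAsFactors = FALSE)
  df[order(-df$score, df$gene), , drop = FALSE]
}

# per-cell log2 CPM, computed with explicit loops
bruteforceLog2CPM <- function(counts, prior = 1) {
  out <- counts
  for (s in seq_len(ncol(counts))) {
    lib <- 0
    for (g in seq_len(nrow(counts))) lib <- lib + counts[g, s]
    for (g in seq_len(nrow(counts)))
      out[g, s] <- log2(counts[g, s] / lib * 1e6 + prior)
  }
  out
}

# small expression fixture with fixed values
tinyExpression <- function() {
  m <- matrix(c(2, 4, 6,
                6, 4, 2,
                5, 5, 5,
                1, 2, 4), nrow = 4, byrow = TRUE,
              dimnames = list(c("up", "down", "flat", "curve"),
                              c("S1", "S2", "S3")))
  SegmentExperiment(m)
}

# seeded random expression container (no planted structure)
randomExpression <- function(nGenes, nSegments = 18, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * nSegments, 4, 1), nGenes, nSegments,
              dimnames = list(sprintf("G%03d", seq_len(nGenes)),
                              paste0("S", seq_len(nSegments))))
  SegmentExperiment(m)
}

# all pairwise vertex distances of a model, rows stacked in segment order
allPairDistances <- function(model) {
  V <- do.call(rbind, lapply(segmentMeshes(model), `[[`, "vertices"))
  as.matrix(dist(V))
}

expect_segatlas_error <- function(expr, subclass) {
  expect_error(expr, class = paste0("segatlas_", subclass))
}
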