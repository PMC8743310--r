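# Session logging, table exports, and the command-line interface.

test_that("session log is append-only and chronological", {
  log <- SessionLog()
  expect_identical(nrow(sessionEvents(log)), 0L)
  e1 <- sessionEvent("select_gene", "Myh6", "normalized", "model1",
                     timestamp = "2026-01-01T10:00:00.000Z")
  e2 <- sessionEvent("heatmap", c("Myh6", "Nppa"), "absolute", "model1",
                     timestamp = "2026-01-01T10:00:01.500Z")
  log <- logEvent(log, e1)
  expect_identical(nrow(sessionEvents(log)), 1L)
  log <- logEvent(log, e2)
  ev <- sessionEvents(log)
  expect_identical(ev$action, c("select_gene", "heatmap"))
  expect_identical(ev$genes[2], "Myh6;Nppa")  # both genes joined by ';'
  expect_identical(ev$view_mode, c("normalized", "absolute"))
  earlier <- sessionEvent("export", timestamp = "2026-01-01T09:59:59.000Z")
  expect_segatlas_error(logEvent(log, earlier), "nonMonotoneTimestamp")
  expect_segatlas_error(sessionEvent("fly_through"), "badAction")
})

test_that("session log TSV round trips and stays valid at each append", {
  path <- withr::local_tempfile(fileext = ".tsv")
  log <- SessionLog()
  stamps <- sprintf("2026-01-01T10:00:0%d.000Z", 0:2)
  acts <- c("select_gene", "snapshot", "export")
  for (i in 1:3) {
    log <- logEvent(log, sessionEvent(acts[i], "Myh6", timestamp = stamps[i]))
    writeSessionLog(log, path)  # flushed after every append
    lines <- readLines(path)
    expect_identical(length(lines), i + 1L)  # header + events so far
    expect_identical(lines[1], "timestamp\taction\tgenes\tview_mode\tmodel_id")
  }
  back <- readSessionLog(path)
  expect_identical(sessionEvents(back), sessionEvents(log))
})

test_that("similarity and heatmap tables export as parseable TSV", {
  se <- randomExpression(8, 18, seed = 6)
  tab <- similarGenes(se, "G001", k = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  exportTable(tab, path)
  lines <- readLines(path)
  expect_identical(length(lines), 6L)  # header + 5 records
  expect_identical(lines[1], "rank\tgene\tsimilarity_percent")
  # scores printed with exactly 2 decimals
  expect_true(all(grepl("^\\d+\\t\\S+\\t\\d+\\.\\d{2}$", lines[-1])))
  back <- read.delim(path, colClasses = c("integer", "character", "numeric"))
  rec <- similarityRecords(tab)
  expect_identical(back$rank, rec$rank)
  expect_identical(back$gene, rec$gene)
  expect_equal(back$similarity_percent, round(rec$similarity_percent, 2))

  hm <- heatmapDiff(se, "G001", "G002", "absolute")
  exportTable(hm, path)
  hl <- readLines(path)
  expect_identical(hl[1], "segment\tdiff\thex_color")
  expect_identical(length(hl), 19L)
  hback <- read.delim(path, colClasses = c("character", "numeric", "character"))
  expect_equal(hback$diff, unname(heatmapDiffs(hm)), tolerance = 1e-5)
  expect_identical(hback$hex_color, unname(segmentHexColors(heatmapColors(hm))))
  # CSV delimiter switch
  exportTable(tab, path, delim = ",")
  expect_identical(readLines(path)[1], "rank,gene,similarity_percent")
  empty <- new("SimilarityTable", query = "q",
               records = S4Vectors::DataFrame(gene = character(),
                                              similarity_percent = numeric()),
               mode = "normalized", skipped = character())
  expect_segatlas_error(exportTable(empty, path), "emptyTable")
})

test_that("a scripted CLI session produces outputs and one event per command", {
  cli <- system.file("cli", "segatlas.R", package = "segatlas")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  expr <- file.path(dir, "expr.csv")
  meshf <- file.path(dir, "mesh.obj")
  session <- file.path(dir, "session.tsv")
  rscript <- file.path(R.home("bin"), "Rscript")
  run <- function(...) {
    res <- suppressWarnings(
      system2(rscript, c(cli, ...), stdout = TRUE, stderr = TRUE))
    status <- attr(res, "status")
    if (is.null(status)) 0L else status
  }
  # simulate writes the dataset + truth table; no session event for setup
  expect_identical(run("simulate", "--n-genes", "40", "--n-segments", "18",
                       "--noise-sd", "0", "--seed", "5", "--out", expr,
                       "--truth", file.path(dir, "truth.tsv")), 0L)
  expect_true(file.exists(expr))
  mesh <- makeSegmentedBlockMesh(18, c(3, 6))
  writeSegmentedMesh(mesh, meshf)
  # three logged commands -> exactly three events, in command order
  expect_identical(run("show", "P1", "--expr", expr, "--mesh", meshf,
                       "--out", file.path(dir, "colored.ply"),
                       "--session", session), 0L)
  expect_identical(run("similar", "P1", "--expr", expr, "-k", "5",
                       "--out", file.path(dir, "similar.tsv"),
                       "--session", session), 0L)
  expect_identical(run("groups", "--expr", expr,
                       "--group-a", "S1,S2,S3", "--group-b", "S10,S11",
                       "-k", "5", "--out", file.path(dir, "groups.tsv"),
                       "--session", session), 0L)
  expect_true(file.exists(file.path(dir, "colored.ply")))
  expect_identical(readLines(file.path(dir, "similar.tsv"))[1],
                   "rank\tgene\tsimilarity_percent")
  ev <- sessionEvents(readSessionLog(session))
  expect_identical(ev$action, c("select_gene", "export", "group_contrast"))
  expect_identical(ev$genes[1], "P1")
  # validation failure exits 2 (unknown gene)
  expect_identical(run("similar", "NOPE", "--expr", expr,
                       "--out", file.path(dir, "x.tsv")), 2L)
  # I/O failure exits 3 (missing dataset)
  expect_identical(run("similar", "P1", "--expr", file.path(dir, "no.csv"),
                       "--out", file.path(dir, "x.tsv")), 3L)
})
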