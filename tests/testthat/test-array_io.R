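test_that("feature tables parse with control types and preserve row order", {
  p <- write_feature_file(c("ProbeName\tControlType\tgProcessedSignal",
                            "p1\t0\t100.0", "p2\t-1\t5.0", "p3\t0\t250.5"))
  scan <- read_feature_table(p)
  expect_s3_class(scan, "feature_scan")
  expect_equal(scan$records$probe_id, c("p1", "p2", "p3"))
  expect_equal(scan$records$control_type, c(0L, -1L, 0L))
  expect_equal(scan$records$raw_signal, c(100, 5, 250.5))
  expect_equal(sum(scan$records$control_type == -1L), 1L)

  empty <- read_feature_table(
    write_feature_file("ProbeName\tControlType\tgProcessedSignal"))
  expect_equal(nrow(empty$records), 0L)
})

test_that("feature-table contract violations are rejected with context", {
  no_ct <- write_feature_file(c("ProbeName\tgProcessedSignal", "p1\t5"))
  expect_error(read_feature_table(no_ct), "ControlType")
  neg <- write_feature_file(c("ProbeName\tControlType\tgProcessedSignal",
                              "p1\t0\t10", "p2\t0\t-3"))
  expect_error(read_feature_table(neg), "row 2")
  dup <- write_feature_file(c("ProbeName\tControlType\tgProcessedSignal",
                              "p1\t0\t10", "p1\t0\t11"))
  expect_error(read_feature_table(dup), "duplicate probe id")
})

test_that("sample sheets mirror the 15-array three-group design", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,group",
               sprintf("ES_%d,ES", 1:6),
               sprintf("OS_%d,OS", 1:6),
               sprintf("CSE_%d,CSE", 1:3)), p)
  sheet <- read_sample_sheet(p)
  expect_equal(nrow(sheet), 15L)
  expect_equal(as.vector(table(sheet$group)[c("ES", "OS", "CSE")]),
               c(6L, 6L, 3L))

  # two-group sheet is valid here; downstream ANOVA refuses it
  two <- sample_sheet(c("a", "b", "c", "d"), c("ES", "ES", "OS", "OS"))
  m <- log2_matrix(matrix(rnorm(8), 2, 4), sample_ids = c("a", "b", "c", "d"))
  expect_error(anova_per_probe(m, two), "three groups")

  expect_error(sample_sheet(c("s1", "s1"), c("ES", "OS")), "duplicate sample id")
  expect_error(sample_sheet("s1", "EPI"), "unknown group")
  expect_equal(sample_sheet("s1", "iPS", group_aliases = c(iPS = "ES"))$group, "ES")
  expect_error(sample_sheet(c("a", "b", "c"), c("ES", "OS", "CSE"),
                            c("x", "x", "x")), "exactly 2")
})

test_that("scans assemble into a raw matrix in sheet order", {
  mk <- function(id, vals) {
    structure(list(array_id = id,
                   records = data.frame(probe_id = paste0("p", 1:4),
                                        control_type = c(0L, 0L, -1L, 0L),
                                        raw_signal = vals)),
              class = "feature_scan")
  }
  sheet <- sample_sheet(c("s1", "s2"), c("ES", "OS"))
  asm <- assemble_matrix(list(mk("s2", 5:8), mk("s1", 1:4)), sheet)
  expect_equal(dim(asm$matrix), c(4L, 2L))
  expect_equal(colnames(asm$matrix$values), c("s1", "s2"))
  expect_equal(asm$matrix$values[, "s1"],
               setNames(c(1, 2, 3, 4), paste0("p", 1:4)))
  expect_equal(asm$matrix$stage, "raw")
  expect_equal(unname(asm$control_types["p3"]), -1L)

  other <- mk("s2", 5:8)
  other$records$probe_id <- paste0("q", 1:4)
  expect_error(assemble_matrix(list(mk("s1", 1:4), other), sheet),
               "probe sets differ")
})

test_that("assembled column sums equal the per-array totals written on disk", {
  cfg <- small_config(n_probes = 300, per_pattern = 5L, seed = 11)
  dir <- tempfile()
  sim <- simulate_experiment(cfg, out_dir = dir)
  scans <- lapply(sim$sheet$sample_id, function(id) {
    read_feature_table(file.path(dir, paste0(id, ".txt")))
  })
  asm <- assemble_matrix(scans, read_sample_sheet(file.path(dir, "sample_sheet.tsv")))
  file_sums <- vapply(scans, function(s) {
    sum(s$records$raw_signal[s$records$control_type == 0L])
  }, numeric(1))
  expect_equal(unname(colSums(asm$matrix$values[
    names(asm$control_types)[asm$control_types == 0L], ])), file_sums)
  expect_equal(ncol(asm$matrix$values), nrow(sim$sheet))
})

test_that("matrix TSV round trip is the identity on values and metadata", {
  set.seed(1)
  m <- expr_matrix(matrix(rexp(60) * 1000, 20, 3,
                          dimnames = list(sprintf("p%02d", 1:20),
                                          c("a", "b", "c"))),
                   scale = "linear", stage = "normalized")
  f <- tempfile()
  write_matrix(m, f)
  m2 <- read_matrix(f)
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  expect_identical(dimnames(m2$values), dimnames(m$values))
  expect_identical(c(m2$scale, m2$stage), c("linear", "normalized"))

  empty <- expr_matrix(matrix(numeric(0), 0, 2,
                              dimnames = list(NULL, c("a", "b"))),
                       scale = "log2", stage = "filtered")
  f2 <- tempfile()
  write_matrix(empty, f2)
  back <- read_matrix(f2)
  expect_equal(nrow(back$values), 0L)
  expect_equal(colnames(back$values), c("a", "b"))
})

test_that("series-matrix dialect parses, rejects unterminated tables, round-trips", {
  p <- tempfile()
  writeLines(c("!Series_title\t\"fixture\"",
               "!series_matrix_table_begin",
               "\"ID_REF\"\t\"GSM1\"\t\"GSM2\"",
               "\"pA\"\t7.1\t7.4",
               "\"pB\"\t3.0\t3.2",
               "\"pC\"\t10\t9.5",
               "!series_matrix_table_end"), p)
  m <- read_series_matrix(p)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m$stage, "normalized")
  expect_equal(m$values["pC", "GSM2"], 9.5)

  bad <- tempfile()
  writeLines(readLines(p)[1:5], bad)
  expect_error(read_series_matrix(bad), "begin/end markers")

  # writer-generated fixture reads back value-identical
  set.seed(2)
  big <- expr_matrix(matrix(rnorm(40, 8, 2), 10, 4,
                            dimnames = list(sprintf("p%d", 1:10),
                                            sprintf("GSM%d", 1:4))),
                     scale = "linear", stage = "normalized")
  f <- tempfile()
  write_series_matrix(big, f)
  back <- read_series_matrix(f, scale = "linear")
  expect_equal(back$values, big$values, tolerance = 1e-12)
})

test_that("annotation tables round-trip including empty GO sets", {
  ann <- annotation_table(c("p1", "p2", "p3"),
                          c("Sox2", "Pou5f1", "Actb"),
                          list(c("GO:0006351", "GO:0003700"),
                               "GO:0006351", character(0)))
  f <- tempfile()
  write_annotation(ann, f)
  back <- read_annotation(f)
  expect_equal(back$probe_id, ann$probe_id)
  expect_equal(back$gene_symbol, ann$gene_symbol)
  expect_equal(back$go_ids, ann$go_ids, ignore_attr = TRUE)
  expect_error(annotation_table(c("p1", "p1"), c("a", "b"), list("", "")),
               "duplicate probe ids")
})

test_that("sample-sheet writer round-trips pairings", {
  sheet <- sample_sheet(c("a", "b", "c", "d", "e", "f"),
                        c("ES", "ES", "OS", "OS", "CSE", "CSE"),
                        c("pr1", "pr1", "", "", "", ""))
  f <- tempfile(fileext = ".tsv")
  write_sample_sheet(sheet, f)
  back <- read_sample_sheet(f)
  expect_equal(as.data.frame(back), as.data.frame(sheet))
})
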