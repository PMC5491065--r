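test_that("group means average technical pairs first, then pairs within group", {
  values <- matrix(c(2, 4, 1, 1, 0, 0, 0), 1,
                   dimnames = list("p1", c("e1", "e2", "o1", "o2",
                                           "c1", "c2", "c3")))
  m <- log2_matrix(values, probe_ids = "p1",
                   sample_ids = colnames(values))
  sheet <- sample_sheet(colnames(values),
                        c("ES", "ES", "OS", "OS", "CSE", "CSE", "CSE"))
  expect_equal(group_means(m, sheet)["p1", ], c(ES = 3, OS = 1, CSE = 0))

  # marking the two ES arrays as one technical pair changes nothing here
  paired <- sample_sheet(colnames(values),
                         c("ES", "ES", "OS", "OS", "CSE", "CSE", "CSE"),
                         c("pairA", "pairA", "", "", "", "", ""))
  expect_equal(group_means(m, paired)["p1", ], c(ES = 3, OS = 1, CSE = 0))

  # unbalanced pairing: pair mean first, then with the unpaired sample
  v2 <- matrix(c(0, 4, 8, 1, 1, 2, 2), 1,
               dimnames = list("p1", colnames(values)))
  m2 <- log2_matrix(v2, probe_ids = "p1", sample_ids = colnames(values))
  sheet2 <- sample_sheet(colnames(values),
                         c("ES", "ES", "ES", "OS", "OS", "CSE", "CSE"),
                         c("pr", "pr", "", "", "", "", ""))
  # ES: mean(pair mean 2, unpaired 8) = 5, not the plain mean 4
  expect_equal(unname(group_means(m2, sheet2)["p1", "ES"]), 5)
})

test_that("unbalanced group means equal brute-force per-group means", {
  set.seed(5)
  values <- matrix(rnorm(10 * 9, 8, 2), 10, 9)
  m <- log2_matrix(values)
  groups <- c("ES", "ES", "ES", "ES", "OS", "OS", "CSE", "CSE", "CSE")
  sheet <- sample_sheet(sprintf("s%d", 1:9), groups)
  gm <- group_means(m, sheet)
  for (g in c("ES", "OS", "CSE")) {
    expect_equal(gm[, g], rowMeans(values[, groups == g]), ignore_attr = TRUE)
  }
})

test_that("per-probe ANOVA matches the classical closed form", {
  sheet <- three_group_sheet(2, 2, 3)
  flat <- log2_matrix(matrix(1, 1, 7), sample_ids = sheet$sample_id)
  st <- anova_per_probe(flat, sheet)
  expect_equal(c(st$F, st$p), c(0, 1))

  sheet2 <- three_group_sheet(2, 2, 2)
  m <- log2_matrix(matrix(c(1, 2, 3, 4, 5, 6), 1),
                   sample_ids = sheet2$sample_id)
  st2 <- anova_per_probe(m, sheet2)
  expect_equal(st2$F, 16)          # SSB = 16, SSW = 1.5, df (2, 3)
  expect_equal(st2$p, pf(16, 2, 3, lower.tail = FALSE))
  # independent route: stats::oneway.test on the same layout
  ow <- oneway.test(x ~ g,
                    data.frame(x = c(1, 2, 3, 4, 5, 6),
                               g = rep(c("a", "b", "c"), each = 2)),
                    var.equal = TRUE)
  expect_equal(st2$F, unname(ow$statistic))
  expect_equal(st2$p, unname(ow$p.value))

  # zero within-group variance with a real between-group effect
  det <- log2_matrix(matrix(c(1, 1, 2, 2, 3, 3), 1),
                     sample_ids = sheet2$sample_id)
  st3 <- anova_per_probe(det, sheet2)
  expect_equal(st3$p, 0)

  expect_error(anova_per_probe(
    log2_matrix(matrix(1:3 * 1.0, 1), sample_ids = sprintf("s%d", 1:3)),
    sample_sheet(sprintf("s%d", 1:3), c("ES", "OS", "CSE"))),
    "degrees of freedom")
})

test_that("null simulation holds the nominal type-I error", {
  set.seed(21)
  sheet <- three_group_sheet(5, 5, 5)
  m <- log2_matrix(matrix(rnorm(1000 * 15, 8, 1), 1000, 15),
                   sample_ids = sheet$sample_id)
  st <- anova_per_probe(m, sheet)
  frac <- mean(st$p < 0.05)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)
  set.seed(6)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("template enumeration has the stated cardinalities and names", {
  b <- generate_templates("binary6")
  expect_equal(nrow(b$templates), 6L)
  expect_true(all(!b$templates$degenerate))
  expect_setequal(b$templates$name,
                  c("ES high", "ES and OS high", "OS and CSE high",
                    "CSE high", "OS high", "ES and CSE high"))
  es <- b$templates[b$templates$name == "ES high", ]
  expect_equal(as.numeric(es[, c("ES", "OS", "CSE")]), c(1, 0, 0))

  t25 <- generate_templates("ternary25")
  expect_equal(nrow(t25$templates), 25L)
  expect_equal(sum(!t25$templates$degenerate), 24L)
  degen <- t25$templates[t25$templates$degenerate, ]
  expect_equal(as.numeric(degen[, c("ES", "OS", "CSE")]), c(0.5, 0.5, 0.5))
})

test_that("pattern assignment is a Pearson argmax with affine invariance", {
  b <- generate_templates("binary6")
  a1 <- assign_pattern(c(1, 0, 0), b)
  expect_equal(a1$group_label, "ES high")
  expect_equal(a1$correlation, 1)

  a2 <- assign_pattern(c(10, 2, 2), b)
  expect_equal(a2$group_label, "ES high")
  expect_equal(a2$correlation, 1)

  expect_equal(assign_pattern(c(5, 5, 1), b)$group_label, "ES and OS high")

  expect_false(assign_pattern(c(4, 4, 4), b)$assignable)

  # affine invariance and agreement with the loop oracle
  set.seed(8)
  mt <- b$templates
  for (i in 1:50) {
    means <- rnorm(3, 8, 3)
    if (sd(means) == 0) next
    got <- assign_pattern(means, b)
    expect_equal(got$template_name, mt$name[pearson_argmax_oracle(means, mt)])
    shifted <- assign_pattern(2.5 * means + 7, b)
    expect_equal(shifted$template_name, got$template_name)
    expect_equal(shifted$correlation, got$correlation)
  }
})

test_that("fold change is high-mean minus low-mean with sign symmetry", {
  expect_equal(fold_change(c(11.16, 0, 0), c(1, 0, 0)), 11.16)
  expect_equal(fold_change(c(3, 3, 1), c(1, 1, 0)), 2)
  set.seed(10)
  for (i in 1:20) {
    means <- rnorm(3, 8, 3)
    expect_equal(fold_change(means, c(0, 1, 1)),
                 -fold_change(means, c(1, 0, 0)))
  }
  # graded template: 0.5 axes excluded from both sides
  expect_equal(fold_change(c(4, 9, 2), c(0, 0.5, 1)), -2)
  expect_error(fold_change(c(1, 2, 3), c(1, 0.5, 0.5)), "undefined")
})

test_that("classification recovers planted patterns and partitions exactly", {
  sheet <- three_group_sheet(6, 6, 3)
  tmpl <- generate_templates("binary6")
  set.seed(12)
  n_planted_per <- 20
  n_null <- 1200
  lv <- as.matrix(tmpl$templates[, c("ES", "OS", "CSE")])
  rows <- list()
  truth <- character(0)
  for (i in 1:6) {
    base <- 8 + 4 * lv[i, ][c(rep(1, 6), rep(2, 6), rep(3, 3))]
    rows[[i]] <- matrix(rnorm(n_planted_per * 15, rep(base, each = n_planted_per),
                              0.25), n_planted_per, 15)
    truth <- c(truth, rep(tmpl$templates$name[i], n_planted_per))
  }
  rows[[7]] <- matrix(rnorm(n_null * 15, 8, 0.25), n_null, 15)
  truth <- c(truth, rep("null", n_null))
  m <- log2_matrix(do.call(rbind, rows), sample_ids = sheet$sample_id)
  asg <- classify_probes(m, sheet, tmpl, probe_q_threshold = 0.10)

  planted <- truth != "null"
  correct <- asg$significant[planted] & !is.na(asg$group[planted]) &
    asg$group[planted] == truth[planted]
  expect_gte(mean(correct), 0.95)
  expect_lte(mean(asg$significant[!planted]), 0.12)

  # the six labels partition the significant assignable probes
  counts <- table(asg$group[asg$significant & asg$assignable])
  expect_equal(sum(counts), attr(asg, "n_significant_assignable"))
  expect_equal(sort(names(counts)), sort(tmpl$templates$name))
})

test_that("gene-level filter enforces strict q/FC boundaries and collapses probes", {
  asg <- data.frame(
    probe_id = c("a", "b", "c", "d", "e"),
    mean_ES = 0, mean_OS = 0, mean_CSE = 0,
    F = 10, p = 0.001,
    q = c(0.04, 0.04, 0.06, 0.01, 0.01),
    significant = TRUE, assignable = TRUE,
    template = "ES high", r = 1,
    log2_fc = c(1.01, 1.00, 3.0, 3.0, 5.0),
    group = "ES high", stringsAsFactors = FALSE)
  class(asg) <- c("pattern_assignments", "data.frame")
  attr(asg, "n_significant_assignable") <- 5L
  ann <- annotation_table(c("a", "b", "c", "d", "e"),
                          c("G1", "G2", "G3", "G4", "G4"),
                          list("", "", "", "", ""))
  out <- gene_level_filter(asg, ann)
  tab <- out[["ES high"]]
  expect_true("G1" %in% tab$gene_symbol)         # q 0.04, fc 1.01: kept
  expect_false("G2" %in% tab$gene_symbol)        # fc exactly 1: strict boundary
  expect_false("G3" %in% tab$gene_symbol)        # q 0.06 over gene threshold
  expect_equal(tab$log2_fc[tab$gene_symbol == "G4"], 5)  # max-|FC| probe wins
  expect_equal(sum(tab$gene_symbol == "G4"), 1L)

  # unannotated probes retained under their probe id, with a message
  ann2 <- annotation_table("a", "G1", list(""))
  expect_message(out2 <- gene_level_filter(asg, ann2), "without gene annotation")
  expect_true("e" %in% out2[["ES high"]]$gene_symbol)
})
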