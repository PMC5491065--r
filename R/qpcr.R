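#' Construct a validated qPCR Ct table
#'
#' Long-format cycle-threshold measurements: one row per gene x sample.
#' The reference gene must be measured in every sample that has any
#' target measurement, and the calibrator group must be present.
#'
#' @param rows data.frame with columns `gene`, `sample_id`, `group`,
#'   `ct` (cycles, > 0). Repeated gene x sample rows are treated as
#'   technical replicates and averaged downstream.
#' @param reference_gene name of the normalization gene (e.g. `"Rplp0"`).
#' @param calibrator_group group whose expression defines fold 1
#'   (default `"ES"`).
#' @return list of class `"ct_table"`.
#' @export
ct_table <- function(rows, reference_gene, calibrator_group = "ES") {
  stopifnot(all(c("gene", "sample_id", "group", "ct") %in% names(rows)))
  if (any(rows$ct <= 0)) stop("Ct values must be positive")
  bad <- setdiff(unique(rows$group), GROUPS)
  if (length(bad) > 0) stop(sprintf("unknown group '%s' in Ct table", bad[1]))
  if (!(calibrator_group %in% rows$group)) {
    stop(sprintf("calibrator group '%s' has no measurements", calibrator_group))
  }
  with_target <- unique(rows$sample_id[rows$gene != reference_gene])
  with_ref <- unique(rows$sample_id[rows$gene == reference_gene])
  orphan <- setdiff(with_target, with_ref)
  if (length(orphan) > 0) {
    stop(sprintf("sample '%s' has target Ct but no reference-gene Ct", orphan[1]))
  }
  structure(list(rows = rows, reference_gene = reference_gene,
                 calibrator_group = calibrator_group),
            class = "ct_table")
}

#' @export
read_ct_table <- function(path, reference_gene, calibrator_group = "ES") {
  rows <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  rows$ct <- as.numeric(rows$ct)
  ct_table(rows, reference_gene, calibrator_group)
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_gene - Ct_reference` (technical-replicate Cts
#' averaged first); `ddCt = dCt - mean(dCt over calibrator-group
#' samples)`; relative quantity `RQ = 2^-ddCt`. Per-group fold change is
#' `2^-mean(ddCt)` under the default geometric convention (so the
#' calibrator group's fold is exactly 1) or the arithmetic mean of RQs.
#'
#' @param tab a `ct_table`.
#' @param gene target gene to quantify.
#' @param summary `"geometric"` (default) or `"arithmetic"` per-group
#'   summarization of the relative quantities.
#' @return list with `per_sample` (data.frame `sample_id`, `group`,
#'   `dct`, `ddct`, `rq`) and `group_folds` (named vector over the
#'   groups measured).
#' @export
delta_delta_ct <- function(tab, gene, summary = c("geometric", "arithmetic")) {
  summary <- match.arg(summary)
  stopifnot(inherits(tab, "ct_table"))
  rows <- tab$rows
  avg_ct <- function(g) {
    sub <- rows[rows$gene == g, , drop = FALSE]
    agg <- stats::aggregate(ct ~ sample_id + group, data = sub, FUN = mean)
    agg
  }
  tgt <- avg_ct(gene)
  if (nrow(tgt) == 0) stop(sprintf("gene '%s' has no Ct measurements", gene))
  ref <- avg_ct(tab$reference_gene)
  i <- match(tgt$sample_id, ref$sample_id)
  if (anyNA(i)) {
    stop(sprintf("sample '%s' lacks a reference-gene Ct",
                 tgt$sample_id[which(is.na(i))[1]]))
  }
  dct <- tgt$ct - ref$ct[i]
  cal <- tgt$group == tab$calibrator_group
  if (!any(cal)) {
    stop(sprintf("gene '%s' not measured in calibrator group '%s'",
                 gene, tab$calibrator_group))
  }
  cal_mean <- mean(dct[cal])
  ddct <- dct - cal_mean
  rq <- 2^(-ddct)
  groups <- intersect(GROUPS, unique(tgt$group))
  folds <- vapply(groups, function(g) {
    sel <- tgt$group == g
    # geometric form written as a difference of group means so the
    # calibrator group comes out as 2^0 = 1 exactly
    if (summary == "geometric") 2^(-(mean(dct[sel]) - cal_mean))
    else mean(rq[sel])
  }, numeric(1))
  list(per_sample = data.frame(sample_id = tgt$sample_id, group = tgt$group,
                               dct = dct, ddct = ddct, rq = rq,
                               row.names = NULL, stringsAsFactors = FALSE),
       group_folds = folds)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison: the exact null distribution when the
#' combined sample size is at most 20 and there are no ties, the normal
#' approximation with tie correction (and continuity correction)
#' otherwise. The reported U is the smaller of the two one-sided U
#' statistics.
#'
#' @param a,b numeric vectors (both nonempty).
#' @return list with `U` and two-sided `p`.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be nonempty")
  n <- length(a) + length(b)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- n <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  u_a <- unname(wt$statistic)
  u <- min(u_a, length(a) * length(b) - u_a)
  p <- unname(wt$p.value)
  if (!is.finite(p)) p <- 1   # fully degenerate ties: no evidence of shift
  list(U = u, p = min(p, 1))
}
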