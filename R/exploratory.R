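#' Principal component analysis of samples
#'
#' Samples are observations and probes variables; probes are centered
#' but not scaled. Scores and variance fractions come from the singular
#' value decomposition of the centered matrix (via [stats::prcomp()]).
#'
#' @param m an `expr_matrix` on the log2 scale with >= 3 samples.
#' @return object of class `"pca_result"`: list with `scores`
#'   (samples x components), `variance_fraction`,
#'   `cumulative_fraction` and `rotation`.
#' @export
pca_samples <- function(m) {
  check_matrix_state(m, scale = "log2")
  if (ncol(m$values) < 3) stop("PCA needs at least 3 samples")
  fit <- stats::prcomp(t(m$values), center = TRUE, scale. = FALSE)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = fit$x,
                 variance_fraction = vf,
                 cumulative_fraction = cumsum(vf),
                 rotation = fit$rotation),
            class = "pca_result")
}

#' Sample-to-sample Pearson correlation matrix
#'
#' @param m an `expr_matrix` with >= 2 samples.
#' @return symmetric samples x samples matrix with unit diagonal;
#'   zero-variance samples get an NA row/column with a warning.
#' @export
sample_correlation <- function(m) {
  check_matrix_state(m)
  x <- m$values
  if (ncol(x) < 2) stop("correlation needs at least 2 samples")
  sds <- apply(x, 2, stats::sd)
  degen <- sds == 0
  out <- matrix(NA_real_, ncol(x), ncol(x),
                dimnames = list(colnames(x), colnames(x)))
  if (any(degen)) {
    warning(sprintf("zero-variance sample(s): %s",
                    paste(colnames(x)[degen], collapse = ", ")))
  }
  if (sum(!degen) >= 1) {
    out[!degen, !degen] <- stats::cor(x[, !degen, drop = FALSE])
  }
  out
}

#' Hierarchical clustering of samples with bootstrap support
#'
#' Base tree: hierarchical clustering of samples under distance
#' `1 - Pearson correlation` (or Euclidean) with average (or complete)
#' linkage. Support: probes are resampled with replacement `n_boot`
#' times; each internal node's bootstrap probability is the fraction of
#' resampled trees containing exactly that node's leaf set.
#'
#' @param m an `expr_matrix` with >= 3 samples.
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @param distance `"correlation"` (1 - Pearson) or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @return object of class `"cluster_tree"`: list with `hclust` (the
#'   base [stats::hclust] tree), `bp` (bootstrap probability per
#'   internal node, in merge order), `leaf_sets`, `distance`, `linkage`,
#'   `n_boot`.
#' @export
bootstrap_cluster <- function(m, n_boot = 1000, seed = NULL,
                              distance = c("correlation", "euclidean"),
                              linkage = c("average", "complete")) {
  check_matrix_state(m)
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (n_boot < 1) stop("n_boot must be >= 1")
  x <- m$values
  if (ncol(x) < 3) stop("clustering needs at least 3 samples")
  if (!is.null(seed)) set.seed(seed)

  cluster_once <- function(v) {
    d <- if (distance == "correlation") stats::as.dist(1 - stats::cor(v))
         else stats::dist(t(v))
    stats::hclust(d, method = linkage)
  }
  node_sets <- function(hc) {
    sets <- vector("list", nrow(hc$merge))
    for (i in seq_len(nrow(hc$merge))) {
      kids <- hc$merge[i, ]
      leaves <- unlist(lapply(kids, function(k) {
        if (k < 0) hc$labels[-k] else sets[[k]]
      }))
      sets[[i]] <- sort(leaves)
    }
    sets
  }
  base <- cluster_once(x)
  base_sets <- node_sets(base)
  keys <- vapply(base_sets, paste, character(1), collapse = "\r")
  hits <- integer(length(keys))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(x), nrow(x), replace = TRUE)
    bs <- node_sets(cluster_once(x[idx, , drop = FALSE]))
    bk <- vapply(bs, paste, character(1), collapse = "\r")
    hits <- hits + (keys %in% bk)
  }
  structure(list(hclust = base, bp = hits / n_boot, leaf_sets = base_sets,
                 distance = distance, linkage = linkage, n_boot = n_boot),
            class = "cluster_tree")
}

#' Newick serialization of a bootstrapped sample tree
#'
#' Writes the base tree with branch lengths from merge heights and the
#' bootstrap probability of each internal node as its node label.
#'
#' @param tree a `cluster_tree`.
#' @param path optional output path; when `NULL` the newick string is
#'   returned.
#' @return the newick string (invisibly when written to `path`).
#' @export
cluster_newick <- function(tree, path = NULL) {
  hc <- tree$hclust
  render <- function(k, parent_height) {
    if (k < 0) {
      sprintf("%s:%.6g", hc$labels[-k], parent_height)
    } else {
      kids <- hc$merge[k, ]
      h <- hc$height[k]
      sprintf("(%s,%s)%.3g:%.6g",
              render(kids[1], h), render(kids[2], h),
              tree$bp[k], parent_height - h)
    }
  }
  root <- nrow(hc$merge)
  kids <- hc$merge[root, ]
  h <- hc$height[root]
  s <- sprintf("(%s,%s)%.3g;", render(kids[1], h), render(kids[2], h),
               tree$bp[root])
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Marker-gene z-score matrix
#'
#' Rows are the probes of the listed marker genes; each row is
#' standardized to `(x - row mean) / row sd` with the population
#' (divide-by-n) standard deviation. Constant rows are zero-filled and
#' flagged.
#'
#' @param m an `expr_matrix`.
#' @param gene_list character vector of marker gene symbols.
#' @param annotation an `annotation_table` mapping probes to symbols.
#' @return genes x samples matrix of z-scores (rownames
#'   `gene_symbol|probe_id`), with attribute `"degenerate"` marking
#'   zero-sd rows.
#' @export
zscore_matrix <- function(m, gene_list, annotation) {
  check_matrix_state(m)
  ann <- annotation[annotation$gene_symbol %in% gene_list, , drop = FALSE]
  ann <- ann[ann$probe_id %in% rownames(m$values), , drop = FALSE]
  if (nrow(ann) == 0) stop("none of the listed genes map to a probe in the matrix")
  x <- m$values[ann$probe_id, , drop = FALSE]
  mu <- rowMeans(x)
  sd_pop <- sqrt(rowMeans((x - mu)^2))
  degen <- sd_pop == 0
  z <- (x - mu) / ifelse(degen, 1, sd_pop)
  z[degen, ] <- 0
  rownames(z) <- paste(ann$gene_symbol, ann$probe_id, sep = "|")
  attr(z, "degenerate") <- stats::setNames(degen, rownames(z))
  z
}
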