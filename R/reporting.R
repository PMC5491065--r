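#' Per-group probe and gene counts
#'
#' Summarizes a classification run: per group-high pattern, the number
#' of significant assignable probes and (when gene tables are given) the
#' number of genes passing the gene-level filter. Probe counts are
#' checked to partition the significant assignable total — the identity
#' the six published pattern groups satisfy. The gene counts double as
#' the Venn-style per-group summary: each gene carries exactly one
#' winning pattern, so the groups are mutually exclusive.
#'
#' @param assignments a `pattern_assignments` data.frame.
#' @param gene_tables optional named list from [gene_level_filter()].
#' @return list with `table` (data.frame `group`, `probe_count`,
#'   `gene_count`), `total_significant_assignable` and
#'   `total_probe_count`.
#' @export
group_counts <- function(assignments, gene_tables = NULL) {
  a <- assignments[assignments$significant &
                     !is.na(assignments$assignable) & assignments$assignable,
                   , drop = FALSE]
  groups <- sort(unique(a$group))
  probe_count <- vapply(groups, function(g) sum(a$group == g), integer(1))
  gene_count <- rep(NA_integer_, length(groups))
  if (!is.null(gene_tables)) {
    gene_count <- vapply(groups, function(g) {
      if (is.null(gene_tables[[g]])) 0L else nrow(gene_tables[[g]])
    }, integer(1))
  }
  total <- attr(assignments, "n_significant_assignable")
  if (is.null(total)) total <- nrow(a)
  if (sum(probe_count) != total) {
    stop("group probe counts do not partition the significant assignable probes")
  }
  list(table = data.frame(group = groups, probe_count = probe_count,
                          gene_count = gene_count, row.names = NULL,
                          stringsAsFactors = FALSE),
       total_significant_assignable = total,
       total_probe_count = sum(probe_count))
}

#' Top-n genes of a group by fold change
#'
#' @param gene_table one group's table from [gene_level_filter()].
#' @param n number of genes to report (default 10).
#' @return the `n` genes with the largest log2 fold change, descending;
#'   ties broken by gene symbol.
#' @export
top_genes <- function(gene_table, n = 10) {
  if (n <= 0) stop("n must be positive")
  ord <- order(-gene_table$log2_fc, gene_table$gene_symbol)
  utils::head(gene_table[ord, , drop = FALSE], n)
}

#' Subset a gene table to transcription factors by GO annotation
#'
#' Keeps the genes whose annotation carries `go_id` (default
#' GO:0006351, "transcription, DNA-dependent"). An optional curated
#' transcription-factor catalogue further refines the result by
#' intersection.
#'
#' @param gene_table one group's table from [gene_level_filter()].
#' @param annotation an `annotation_table`.
#' @param go_id GO accession selecting candidate transcription factors.
#' @param tf_catalogue optional character vector of gene symbols; when
#'   supplied the GO hits are intersected with it.
#' @return the transcription-factor subset of `gene_table`, same
#'   ordering.
#' @export
subset_transcription_factors <- function(gene_table, annotation,
                                         go_id = "GO:0006351",
                                         tf_catalogue = NULL) {
  has_go <- vapply(annotation$go_ids, function(g) go_id %in% g, logical(1))
  if (!any(has_go)) {
    warning(sprintf("GO id '%s' absent from the annotation", go_id))
    return(gene_table[0, , drop = FALSE])
  }
  go_genes <- unique(annotation$gene_symbol[has_go])
  keep <- gene_table$gene_symbol %in% go_genes
  if (!is.null(tf_catalogue)) {
    keep <- keep & gene_table$gene_symbol %in% tf_catalogue
  }
  gene_table[keep, , drop = FALSE]
}
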