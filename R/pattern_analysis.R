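#' Per-probe group means over the (ES, OS, CSE) axis
#'
#' Technical-duplicate pairs declared in the sheet are averaged first;
#' the per-group mean is then taken over pair means and unpaired
#' samples. For balanced pairs this equals the plain per-group mean.
#'
#' @param m an `expr_matrix` on the log2 scale.
#' @param sheet a `sample_sheet` covering the matrix columns; all three
#'   groups must be present.
#' @return numeric matrix, probes x 3, columns `ES`, `OS`, `CSE`.
#' @export
group_means <- function(m, sheet) {
  check_matrix_state(m, scale = "log2")
  sheet <- sheet[match(colnames(m$values), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) {
    stop("sample sheet does not cover every matrix column")
  }
  missing <- setdiff(GROUPS, unique(sheet$group))
  if (length(missing) > 0) {
    stop(sprintf("group '%s' has no samples", missing[1]))
  }
  # collapse technical pairs to one pseudo-sample each
  unit <- ifelse(nzchar(sheet$duplicate_pair_id),
                 paste0("pair:", sheet$duplicate_pair_id),
                 paste0("sample:", sheet$sample_id))
  units <- unique(unit)
  collapsed <- vapply(units, function(u) {
    rowMeans(m$values[, unit == u, drop = FALSE])
  }, numeric(nrow(m$values)))
  collapsed <- matrix(collapsed, nrow = nrow(m$values),
                      dimnames = list(rownames(m$values), units))
  unit_group <- sheet$group[match(units, unit)]
  out <- vapply(GROUPS, function(g) {
    rowMeans(collapsed[, unit_group == g, drop = FALSE])
  }, numeric(nrow(m$values)))
  matrix(out, nrow = nrow(m$values), ncol = 3,
         dimnames = list(rownames(m$values), GROUPS))
}

#' One-way fixed-effects ANOVA for every probe
#'
#' Classical three-group one-way layout on log2 values, computed in
#' closed form across all probes at once:
#' `F = (SSB/(k-1)) / (SSW/(n-k))`, p from the F distribution with
#' `(k-1, n-k)` degrees of freedom. `SSW = 0` with `SSB > 0` yields
#' `p = 0`; `SSB = 0` yields `F = 0`, `p = 1`. All array columns count
#' as observations.
#'
#' @param m an `expr_matrix` on the log2 scale.
#' @param sheet a `sample_sheet` covering the matrix columns.
#' @return data.frame `probe_id`, `F`, `p`.
#' @export
anova_per_probe <- function(m, sheet) {
  check_matrix_state(m, scale = "log2")
  sheet <- sheet[match(colnames(m$values), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) {
    stop("sample sheet does not cover every matrix column")
  }
  grp <- factor(sheet$group, levels = GROUPS)
  grp <- droplevels(grp)
  k <- nlevels(grp)
  n <- length(grp)
  if (k < 3) stop("one-way ANOVA needs all three groups present")
  if (n <= k) stop(sprintf("degrees of freedom exhausted: n = %d, k = %d", n, k))
  x <- m$values
  n_g <- as.vector(table(grp))
  # group sums via indicator matrix multiplication
  ind <- stats::model.matrix(~ grp - 1)
  gsum <- x %*% ind
  gmean <- sweep(gsum, 2, n_g, "/")
  grand <- rowMeans(x)
  ssb <- rowSums(sweep((gmean - grand)^2, 2, n_g, "*"))
  sst <- rowSums((x - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  Fv <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(Fv, k - 1, n - k, lower.tail = FALSE)
  zero_b <- ssb == 0
  Fv[zero_b] <- 0
  p[zero_b] <- 1
  zero_w <- !zero_b & ssw == 0
  Fv[zero_w] <- Inf
  p[zero_w] <- 0
  data.frame(probe_id = rownames(x), F = Fv, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: sort p ascending, `q_(i) = min_{j >= i}
#' p_(j) * m / j`, capped at 1, mapped back to input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Enumerate candidate expression templates over (ES, OS, CSE)
#'
#' `binary6`: the six non-constant members of \{0,1\}^3, named by which
#' groups sit at the high level. `ternary25`: the 25 non-constant members
#' of \{0, 0.5, 1\}^3; the zero-variance member (0.5, 0.5, 0.5) is
#' flagged degenerate and excluded from matching, leaving 24 matchable
#' templates. Graded (non-binary) templates get systematic names and a
#' coarse label from the binary template they correlate with most.
#'
#' Row order encodes the matching tie-break: binary templates first,
#' then lexicographically smaller level vectors.
#'
#' @param mode `"binary6"` or `"ternary25"`.
#' @return object of class `"template_set"`: list with `mode` and a
#'   data.frame `templates` (`name`, `ES`, `OS`, `CSE`, `degenerate`,
#'   `binary`, `label`).
#' @export
generate_templates <- function(mode = c("binary6", "ternary25")) {
  mode <- match.arg(mode)
  levels_set <- if (mode == "binary6") c(0, 1) else c(0, 0.5, 1)
  grid <- expand.grid(ES = levels_set, OS = levels_set, CSE = levels_set,
                      KEEP.OUT.ATTRS = FALSE)
  constant <- apply(grid, 1, function(v) length(unique(v)) == 1)
  keep <- !(constant & grid$ES %in% c(0, 1))   # drop (0,0,0) and (1,1,1)
  grid <- grid[keep, , drop = FALSE]
  degenerate <- apply(grid, 1, stats::sd) == 0  # (0.5,0.5,0.5) only
  binary <- apply(grid, 1, function(v) all(v %in% c(0, 1)))

  binary_labels <- c("1,0,0" = "ES high", "1,1,0" = "ES and OS high",
                     "0,1,1" = "OS and CSE high", "0,0,1" = "CSE high",
                     "0,1,0" = "OS high", "1,0,1" = "ES and CSE high")
  key <- apply(grid, 1, paste, collapse = ",")
  name <- ifelse(binary, binary_labels[key],
                 paste0("graded(", key, ")"))
  bin_mat <- do.call(rbind, lapply(names(binary_labels), function(k) {
    as.numeric(strsplit(k, ",")[[1]])
  }))
  label <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (binary[i]) {
      label[i] <- binary_labels[key[i]]
    } else if (degenerate[i]) {
      label[i] <- NA_character_
    } else {
      r <- apply(bin_mat, 1, function(t) pearson3(as.numeric(grid[i, ]), t))
      label[i] <- paste0(name[i], " ~ ", binary_labels[which.max(r)])
    }
  }
  templates <- data.frame(name = unname(name), ES = grid$ES, OS = grid$OS,
                          CSE = grid$CSE, degenerate = degenerate,
                          binary = binary, label = unname(label),
                          row.names = NULL, stringsAsFactors = FALSE)
  # matching preference: binary first, then lexicographically smaller levels
  ord <- order(!templates$binary, templates$ES, templates$OS, templates$CSE)
  templates <- templates[ord, , drop = FALSE]
  rownames(templates) <- NULL
  structure(list(mode = mode, templates = templates), class = "template_set")
}

# Pearson correlation of two length-3 vectors, |r| capped at 1;
# NA when either vector has zero variance.
pearson3 <- function(a, b) {
  ca <- a - mean(a); cb <- b - mean(b)
  da <- sqrt(sum(ca^2)); db <- sqrt(sum(cb^2))
  if (da == 0 || db == 0) return(NA_real_)
  max(min(sum(ca * cb) / (da * db), 1), -1)
}

# standardized matchable-template matrix (templates x 3) plus metadata,
# in tie-break preference order
matchable_templates <- function(templates) {
  tm <- templates$templates
  tm <- tm[!tm$degenerate, , drop = FALSE]
  lv <- as.matrix(tm[, GROUPS])
  cl <- lv - rowMeans(lv)
  zt <- cl / sqrt(rowSums(cl^2))
  list(meta = tm, z = zt)
}

#' Assign the best-matching template to one mean profile
#'
#' Computes the Pearson correlation between the length-3 mean vector and
#' every non-degenerate template and picks the argmax. Ties prefer
#' binary templates, then the lexicographically smallest level vector.
#' Constant mean vectors are unassignable.
#'
#' @param means numeric length-3 vector of (ES, OS, CSE) log2 means.
#' @param templates a `template_set`.
#' @return list with `template_name`, `levels`, `correlation`,
#'   `group_label` and `assignable`; unassignable profiles return
#'   `assignable = FALSE` and NA fields.
#' @export
assign_pattern <- function(means, templates) {
  stopifnot(length(means) == 3)
  mt <- matchable_templates(templates)
  cm <- means - mean(means)
  dm <- sqrt(sum(cm^2))
  if (dm == 0) {
    return(list(template_name = NA_character_, levels = rep(NA_real_, 3),
                correlation = NA_real_, group_label = NA_character_,
                assignable = FALSE))
  }
  r <- as.vector(mt$z %*% (cm / dm))
  r <- pmin(pmax(r, -1), 1)
  win <- which.max(r)   # first max = preference order
  list(template_name = mt$meta$name[win],
       levels = as.numeric(mt$meta[win, GROUPS]),
       correlation = r[win],
       group_label = mt$meta$label[win],
       assignable = TRUE)
}

#' Log2 fold change of a mean profile under a template
#'
#' Mean of the group means where the template level is 1, minus the mean
#' where it is 0; 0.5-level axes contribute to neither side.
#'
#' @param means numeric length-3 (ES, OS, CSE) log2 means.
#' @param levels numeric length-3 template levels over \{0, 0.5, 1\}.
#' @return log2 fold change (high minus low).
#' @export
fold_change <- function(means, levels) {
  stopifnot(length(means) == 3, length(levels) == 3)
  hi <- levels == 1
  lo <- levels == 0
  if (!any(hi) || !any(lo)) {
    stop("fold change undefined: template needs both a 1-level and a 0-level axis")
  }
  mean(means[hi]) - mean(means[lo])
}

# vectorized fold change; NA where a template lacks a 1- or 0-side
fold_change_matrix <- function(means_mat, levels_mat) {
  hi <- levels_mat == 1
  lo <- levels_mat == 0
  hi_mean <- rowSums(means_mat * hi) / rowSums(hi)
  lo_mean <- rowSums(means_mat * lo) / rowSums(lo)
  out <- hi_mean - lo_mean
  out[rowSums(hi) == 0 | rowSums(lo) == 0] <- NA_real_
  out
}

#' Classify probes into group-high expression patterns
#'
#' The full per-probe analysis: one-way ANOVA over the three groups,
#' Benjamini-Hochberg q-values across all probes, then for every probe
#' with `q < probe_q_threshold` a Pearson template match of its
#' (ES, OS, CSE) mean profile and the corresponding log2 fold change.
#' In `binary6` mode the six group labels partition the significant,
#' assignable probes.
#'
#' @param m a preprocessed, filtered `expr_matrix` on the log2 scale.
#' @param sheet a `sample_sheet`.
#' @param templates a `template_set` (default `binary6`).
#' @param probe_q_threshold probe-level FDR threshold (default 0.10).
#' @return data.frame of class `"pattern_assignments"`, one row per
#'   probe: `probe_id`, `mean_ES`, `mean_OS`, `mean_CSE`, `F`, `p`, `q`,
#'   `significant`, `assignable`, `template`, `r`, `log2_fc`, `group`.
#'   Attribute `"n_significant_assignable"` carries the partition total.
#' @export
classify_probes <- function(m, sheet, templates = generate_templates("binary6"),
                            probe_q_threshold = 0.10) {
  gm <- group_means(m, sheet)
  st <- anova_per_probe(m, sheet)
  st$q <- bh_adjust(st$p)
  sig <- st$q < probe_q_threshold

  n <- nrow(gm)
  template <- rep(NA_character_, n)
  rr <- rep(NA_real_, n)
  fc <- rep(NA_real_, n)
  grp <- rep(NA_character_, n)
  assignable <- rep(NA, n)

  if (any(sig)) {
    mt <- matchable_templates(templates)
    sub <- gm[sig, , drop = FALSE]
    cm <- sub - rowMeans(sub)
    dm <- sqrt(rowSums(cm^2))
    ok <- dm > 0
    assignable[sig] <- ok
    if (any(ok)) {
      z <- cm[ok, , drop = FALSE] / dm[ok]
      rmat <- z %*% t(mt$z)
      rmat <- pmin(pmax(rmat, -1), 1)
      win <- max.col(rmat, ties.method = "first")
      idx_sig <- which(sig)[ok]
      template[idx_sig] <- mt$meta$name[win]
      rr[idx_sig] <- rmat[cbind(seq_along(win), win)]
      grp[idx_sig] <- mt$meta$label[win]
      fc[idx_sig] <- fold_change_matrix(
        gm[idx_sig, , drop = FALSE],
        as.matrix(mt$meta[win, GROUPS]))
    }
  }
  out <- data.frame(probe_id = st$probe_id,
                    mean_ES = gm[, "ES"], mean_OS = gm[, "OS"],
                    mean_CSE = gm[, "CSE"],
                    F = st$F, p = st$p, q = st$q,
                    significant = sig, assignable = assignable,
                    template = template, r = rr, log2_fc = fc, group = grp,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_significant_assignable") <-
    sum(sig & !is.na(assignable) & assignable)
  attr(out, "probe_q_threshold") <- probe_q_threshold
  attr(out, "mode") <- templates$mode
  class(out) <- c("pattern_assignments", "data.frame")
  out
}

#' Filter and collapse pattern assignments to per-group gene tables
#'
#' Probes are mapped to gene symbols through the annotation (unannotated
#' probes keep their probe id as symbol, with a message); per gene the
#' probe with the largest |log2 fold change| is kept; genes survive iff
#' `q < gene_q_threshold` and `|log2_fc| > min_abs_log2fc` (linear fold
#' change > 2 corresponds to `min_abs_log2fc = 1`, the default; both
#' boundaries are strict).
#'
#' @param assignments a `pattern_assignments` data.frame.
#' @param annotation an `annotation_table`.
#' @param gene_q_threshold gene-level FDR threshold (default 0.05).
#' @param min_abs_log2fc minimum |log2 fold change|, exclusive
#'   (default 1).
#' @return named list, one data.frame per group label present, each with
#'   columns `gene_symbol`, `probe_id`, `q`, `log2_fc`, `group`, sorted
#'   by descending `log2_fc`.
#' @export
gene_level_filter <- function(assignments, annotation,
                              gene_q_threshold = 0.05, min_abs_log2fc = 1.0) {
  a <- assignments[assignments$significant &
                     !is.na(assignments$assignable) & assignments$assignable &
                     !is.na(assignments$log2_fc), , drop = FALSE]
  sym <- annotation$gene_symbol[match(a$probe_id, annotation$probe_id)]
  n_unann <- sum(is.na(sym) | !nzchar(sym))
  if (n_unann > 0) {
    message(sprintf("%d probes without gene annotation kept under their probe id",
                    n_unann))
  }
  sym[is.na(sym) | !nzchar(sym)] <- a$probe_id[is.na(sym) | !nzchar(sym)]
  a$gene_symbol <- sym
  keep <- a$q < gene_q_threshold & abs(a$log2_fc) > min_abs_log2fc
  a <- a[keep, , drop = FALSE]
  out <- list()
  for (g in sort(unique(a$group))) {
    sub <- a[a$group == g, , drop = FALSE]
    # per gene: probe with the largest |fold change| (stable on ties:
    # order by |fc| desc then probe id)
    sub <- sub[order(-abs(sub$log2_fc), sub$probe_id), , drop = FALSE]
    sub <- sub[!duplicated(sub$gene_symbol), , drop = FALSE]
    sub <- sub[order(-sub$log2_fc, sub$gene_symbol), , drop = FALSE]
    out[[g]] <- data.frame(gene_symbol = sub$gene_symbol,
                           probe_id = sub$probe_id, q = sub$q,
                           log2_fc = sub$log2_fc, group = sub$group,
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}
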