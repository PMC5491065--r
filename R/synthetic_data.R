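#' Configuration of a synthetic three-group microarray experiment
#'
#' The defaults emulate the 15-array study layout: 6 embryonic stem
#' cell arrays (2 newly hybridized plus 4 public), 6 otosphere arrays
#' and 3 cochlear sensory epithelium arrays; 60,000 regular probes with
#' 1,000 dedicated negative controls; 100 probes planted per binary
#' group-high pattern at log2 effect size 4 with biological noise sd
#' 0.25; raw intensities follow the normexp convolution (exponential
#' signal mean 80 on top of a Normal(50, 10^2) background) so
#' background-correction parameter recovery is meaningful; 10% of null
#' probes are unexpressed (background-only) to exercise the
#' negative-control filter; 10% of probes are flagged GO:0006351
#' transcription factors.
#'
#' @param n_probes number of regular probes.
#' @param n_neg_controls number of negative-control probes.
#' @param design data.frame `group`, `n_samples`, `paired` (logical:
#'   hybridize the group's samples as technical-duplicate pairs; needs
#'   an even `n_samples`).
#' @param planted named integer vector: probes to plant per binary
#'   pattern label (names from `generate_templates("binary6")`).
#' @param effect_size log2 effect added on pattern-high groups.
#' @param noise_sd biological log2 noise sd per array.
#' @param background named vector `c(alpha, mu, sigma)`: exponential
#'   signal mean and normal background mean/sd on the linear scale.
#' @param baseline_log2 log2 expression of an expressed probe at the
#'   pattern-low level.
#' @param unexpressed_fraction fraction of null probes with no true
#'   signal (raw intensity is background only).
#' @param tf_fraction fraction of probes annotated with GO:0006351.
#' @param seed integer seed fixing the whole artifact chain.
#' @return validated list of class `"sim_config"`.
#' @export
simulation_config <- function(n_probes = 60000,
                              n_neg_controls = 1000,
                              design = data.frame(
                                group = c("ES", "OS", "CSE"),
                                n_samples = c(6L, 6L, 3L),
                                paired = FALSE),
                              planted = stats::setNames(
                                rep(100L, 6),
                                generate_templates("binary6")$templates$name),
                              effect_size = 4,
                              noise_sd = 0.25,
                              background = c(alpha = 80, mu = 50, sigma = 10),
                              baseline_log2 = 8,
                              unexpressed_fraction = 0.10,
                              tf_fraction = 0.10,
                              seed = 1L) {
  stopifnot(n_probes >= 1, n_neg_controls >= 1,
            all(design$group %in% GROUPS), all(design$n_samples >= 1),
            noise_sd > 0, background[["sigma"]] > 0, background[["alpha"]] > 0,
            unexpressed_fraction >= 0, unexpressed_fraction <= 1,
            tf_fraction >= 0, tf_fraction <= 1)
  tmpl_names <- generate_templates("binary6")$templates$name
  if (!all(names(planted) %in% tmpl_names)) {
    stop("planted pattern names must be binary group-high labels")
  }
  if (sum(planted) > n_probes) {
    stop("planted probe counts exceed n_probes")
  }
  if (any(design$paired & design$n_samples %% 2 != 0)) {
    stop("paired groups need an even number of samples")
  }
  structure(list(n_probes = as.integer(n_probes),
                 n_neg_controls = as.integer(n_neg_controls),
                 design = design, planted = planted,
                 effect_size = effect_size, noise_sd = noise_sd,
                 background = background, baseline_log2 = baseline_log2,
                 unexpressed_fraction = unexpressed_fraction,
                 tf_fraction = tf_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a complete synthetic microarray experiment
#'
#' Generates per-array raw feature scans, a sample sheet, a probe
#' annotation and a truth table with known planted structure. Per probe
#' and array, the true log2 expression is
#' `baseline + effect * pattern_level(group) + Normal(0, noise_sd)`;
#' the linear signal `2^log2` is summed with a fresh
#' `Normal(mu, sigma^2)` background draw and floored at 0. Unexpressed
#' probes and negative controls carry background draws only. Technical
#' duplicates share the biological draw and differ by an extra
#' `Normal(0, noise_sd / 2)` technical term. The same seed reproduces
#' every artifact byte for byte.
#'
#' @param config a `sim_config`.
#' @param out_dir optional directory; when given, feature tables, sample
#'   sheet, annotation and truth table are also written as TSV through
#'   the package writers.
#' @return list with `scans` (list of `feature_scan`), `sheet`,
#'   `annotation`, `truth` (data.frame `probe_id`, `gene_symbol`,
#'   `planted_pattern`, `effect_size`, `is_tf`) and `config`.
#' @export
simulate_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  np <- config$n_probes
  probe_ids <- sprintf("PR%06d", seq_len(np))
  nc_ids <- sprintf("NC%06d", seq_len(config$n_neg_controls))
  gene_ids <- sprintf("Gene%06d", seq_len(np))

  # sample sheet
  sheet_rows <- do.call(rbind, lapply(seq_len(nrow(config$design)), function(i) {
    g <- config$design$group[i]
    ns <- config$design$n_samples[i]
    ids <- sprintf("%s_%d", g, seq_len(ns))
    pair <- if (config$design$paired[i]) {
      sprintf("%s_pair%d", g, rep(seq_len(ns / 2), each = 2))
    } else rep("", ns)
    data.frame(sample_id = ids, group = g, duplicate_pair_id = pair,
               stringsAsFactors = FALSE)
  }))
  sheet <- sample_sheet(sheet_rows$sample_id, sheet_rows$group,
                        sheet_rows$duplicate_pair_id)

  # planted truth
  tmpl <- generate_templates("binary6")$templates
  pattern <- rep("null", np)
  planted_idx <- sample.int(np, sum(config$planted))
  pattern[planted_idx] <- rep(names(config$planted), config$planted)
  nulls <- which(pattern == "null")
  n_unexpr <- round(config$unexpressed_fraction * length(nulls))
  unexpr <- sample(nulls, n_unexpr)
  pattern[unexpr] <- "unexpressed"
  is_tf <- seq_len(np) %in% sample.int(np, round(config$tf_fraction * np))
  truth <- data.frame(probe_id = probe_ids, gene_symbol = gene_ids,
                      planted_pattern = pattern,
                      effect_size = ifelse(pattern %in% tmpl$name,
                                           config$effect_size, 0),
                      is_tf = is_tf, stringsAsFactors = FALSE)

  # per-probe per-group true baseline log2 (before noise)
  level <- matrix(0, np, 3, dimnames = list(NULL, GROUPS))
  for (i in seq_len(nrow(tmpl))) {
    sel <- pattern == tmpl$name[i]
    if (any(sel)) {
      level[sel, ] <- matrix(as.numeric(tmpl[i, GROUPS]), sum(sel), 3,
                             byrow = TRUE)
    }
  }
  true_log2 <- config$baseline_log2 + config$effect_size * level
  expressed <- pattern != "unexpressed"

  # biological draws per hybridization unit, technical term per array
  unit <- ifelse(nzchar(sheet$duplicate_pair_id),
                 sheet$duplicate_pair_id, sheet$sample_id)
  units <- unique(unit)
  bio <- matrix(stats::rnorm(np * length(units), 0, config$noise_sd),
                np, length(units), dimnames = list(NULL, units))
  bg <- config$background
  scans <- vector("list", nrow(sheet))
  for (j in seq_len(nrow(sheet))) {
    lg <- true_log2[, sheet$group[j]] + bio[, unit[j]]
    if (nzchar(sheet$duplicate_pair_id[j])) {
      lg <- lg + stats::rnorm(np, 0, config$noise_sd / 2)
    }
    signal <- ifelse(expressed, 2^lg, 0)
    raw <- pmax(signal + stats::rnorm(np, bg[["mu"]], bg[["sigma"]]), 0)
    nc_raw <- pmax(stats::rnorm(config$n_neg_controls,
                                bg[["mu"]], bg[["sigma"]]), 0)
    scans[[j]] <- structure(
      list(array_id = sheet$sample_id[j],
           records = data.frame(
             probe_id = c(probe_ids, nc_ids),
             control_type = c(rep(0L, np), rep(-1L, config$n_neg_controls)),
             raw_signal = c(raw, nc_raw),
             stringsAsFactors = FALSE)),
      class = "feature_scan")
  }

  annotation <- annotation_table(
    probe_id = probe_ids, gene_symbol = gene_ids,
    go_ids = ifelse(is_tf, "GO:0006351", ""))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in scans) {
      write_feature_table(s, file.path(out_dir, paste0(s$array_id, ".txt")))
    }
    write_sample_sheet(sheet, file.path(out_dir, "sample_sheet.tsv"))
    write_annotation(annotation, file.path(out_dir, "annotation.tsv"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  }
  list(scans = scans, sheet = sheet, annotation = annotation,
       truth = truth, config = config)
}

#' Run the full preprocessing + classification pipeline on scans
#'
#' Convenience wrapper: assemble, background-correct, quantile
#' normalize, filter against negative controls, log2-transform and
#' classify. Exposes the main tuning points of each stage.
#'
#' @param scans list of `feature_scan` objects.
#' @param sheet a `sample_sheet`.
#' @param templates a `template_set`.
#' @param bg_method,bg_offset background-correction settings, see
#'   [background_correct()].
#' @param percentile,brightness_factor,min_arrays filter settings, see
#'   [negctrl_filter()].
#' @param probe_q_threshold probe-level FDR threshold.
#' @return list with `assignments`, `matrix` (filtered, log2),
#'   `filter` (the [negctrl_filter()] result) and `normalized` (the
#'   normalized linear matrix including control probes).
#' @export
run_pipeline <- function(scans, sheet,
                         templates = generate_templates("binary6"),
                         bg_method = "normexp_moments", bg_offset = 16,
                         percentile = 95, brightness_factor = 1.10,
                         min_arrays = 3, probe_q_threshold = 0.10) {
  asm <- assemble_matrix(scans, sheet)
  bc <- background_correct(asm$matrix, control_types = asm$control_types,
                           method = bg_method, offset = bg_offset)
  nm <- quantile_normalize(bc)
  fl <- negctrl_filter(nm, asm$control_types, percentile = percentile,
                       brightness_factor = brightness_factor,
                       min_arrays = min_arrays)
  lm <- log2_transform(fl$matrix)
  assignments <- classify_probes(lm, sheet, templates = templates,
                                 probe_q_threshold = probe_q_threshold)
  list(assignments = assignments, matrix = lm, filter = fl, normalized = nm)
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' `Ct = ct_base - log2(fold(gene, group)) + Normal(0, ct_sd)`; the
#' reference gene has fold 1 in every group, so the 2^-ddCt arithmetic
#' inverts the planted folds exactly as `ct_sd -> 0`.
#'
#' @param folds numeric matrix of planted fold changes, genes x groups
#'   (colnames from `ES`, `OS`, `CSE`); all entries > 0.
#' @param n_replicates biological replicates per group.
#' @param ct_sd measurement noise sd in cycles.
#' @param reference_gene name of the reference gene (fold 1 everywhere).
#' @param calibrator_group group defining fold 1.
#' @param ct_base baseline cycle threshold.
#' @param seed integer seed.
#' @return a `ct_table`.
#' @export
simulate_ct <- function(folds, n_replicates = 3, ct_sd = 0.05,
                        reference_gene = "Rplp0", calibrator_group = "ES",
                        ct_base = 20, seed = 1L) {
  stopifnot(is.matrix(folds), all(folds > 0),
            all(colnames(folds) %in% GROUPS))
  set.seed(seed)
  genes <- c(rownames(folds), reference_gene)
  rows <- do.call(rbind, lapply(colnames(folds), function(g) {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      sid <- sprintf("%s_rep%d", g, r)
      data.frame(gene = genes, sample_id = sid, group = g,
                 ct = ct_base -
                   log2(c(folds[, g], 1)) +
                   stats::rnorm(length(genes), 0, ct_sd),
                 stringsAsFactors = FALSE)
    }))
  }))
  ct_table(rows, reference_gene, calibrator_group)
}

#' Score classification recovery against planted truth
#'
#' @param truth truth table from [simulate_experiment()].
#' @param assignments a `pattern_assignments` data.frame (probe universe
#'   must be a subset of the truth's).
#' @return list with `confusion` (planted pattern x assigned group
#'   counts over significant assignable planted probes), `recovery`
#'   (per-pattern fraction of planted probes that are significant and
#'   correctly labeled), `overall_recovery`, `null_fp_rate` (fraction of
#'   null baseline probes called significant) and
#'   `complementary_confusions` (count of planted probes assigned the
#'   complementary pattern, e.g. (1,0,0) vs (0,1,1)).
#' @export
recovery_report <- function(truth, assignments) {
  if (!all(assignments$probe_id %in% truth$probe_id)) {
    stop("assignment probes missing from the truth table")
  }
  tr <- truth[match(assignments$probe_id, truth$probe_id), , drop = FALSE]
  planted_names <- setdiff(unique(tr$planted_pattern), c("null", "unexpressed"))
  sig_ok <- assignments$significant &
    !is.na(assignments$assignable) & assignments$assignable

  planted_all <- truth$planted_pattern %in% planted_names
  conf <- table(planted = tr$planted_pattern[tr$planted_pattern %in%
                                               planted_names & sig_ok],
                assigned = assignments$group[tr$planted_pattern %in%
                                               planted_names & sig_ok])
  recovery <- vapply(planted_names, function(p) {
    n_planted <- sum(truth$planted_pattern == p)
    hit <- sum(tr$planted_pattern == p & sig_ok & assignments$group == p,
               na.rm = TRUE)
    hit / n_planted
  }, numeric(1))
  overall <- sum(tr$planted_pattern %in% planted_names & sig_ok &
                   assignments$group == tr$planted_pattern, na.rm = TRUE) /
    sum(truth$planted_pattern %in% planted_names)

  null_probes <- tr$planted_pattern == "null"
  fp <- if (any(null_probes)) mean(assignments$significant[null_probes]) else NA_real_

  comp_map <- c("ES high" = "OS and CSE high", "OS high" = "ES and CSE high",
                "CSE high" = "ES and OS high",
                "OS and CSE high" = "ES high", "ES and CSE high" = "OS high",
                "ES and OS high" = "CSE high")
  comp <- sum(tr$planted_pattern %in% planted_names & sig_ok &
                assignments$group == comp_map[tr$planted_pattern],
              na.rm = TRUE)
  list(confusion = conf, recovery = recovery, overall_recovery = overall,
       null_fp_rate = fp, complementary_confusions = comp)
}
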