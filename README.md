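# otopattern

Otospheres — floating spheres grown from dissociated neonatal cochlear
cells — are enriched for otic stem/progenitor cells. A natural question is
where their transcriptome sits between the tissue they came from (the
cochlear sensory epithelium, CSE) and a pluripotent comparator (embryonic
stem cells, ES). `otopattern` is an R package for exactly this kind of
three-group, single-channel microarray comparison: it classifies every
probe into one of six "group-high" expression patterns (ES high, ES and
OS high, OS and CSE high, CSE high, OS high, ES and CSE high) and reduces
the result to per-group gene tables, top-fold-change rankings and
GO-based transcription-factor subsets.

The package is aimed at analysts who have per-array feature-extraction
exports (or a GEO series matrix) and a three-group sample sheet, and want
a reproducible, tested path from raw intensities to pattern-classified
gene lists — plus a synthetic-data generator with planted truth so every
stage can be validated without touching real data.

## The method

For arrays *j = 1..n* in groups *g ∈ {ES, OS, CSE}*:

1. **Preprocessing.** Per-array background correction under the normexp
   convolution (observed = Exponential(α) signal + Normal(μ, σ²)
   background, fitted by the method of moments, values replaced by
   E[signal | observed] + offset), quantile normalization across arrays,
   then probe filtering against the negative controls: a probe is kept
   iff it is at least 10% brighter than the array-wise 95th percentile of
   the negative-control intensities on at least 3 arrays.
2. **Per-probe ANOVA + FDR.** On log2 values, a one-way fixed-effects
   ANOVA per probe, F = (SSB/(k−1))/(SSW/(n−k)), with
   Benjamini–Hochberg q-values across probes; probes with q < 0.1 are
   carried forward.
3. **Template matching.** Each significant probe's mean profile
   m = (m_ES, m_OS, m_CSE) (technical duplicates averaged first) is
   correlated with every candidate template t ∈ {0,1}³ \ {000, 111}
   (six patterns; a 25-member {0, ½, 1}³ graded set is also available)
   and assigned to argmax_t r(m, t). The winning template names the
   probe's group; its log2 fold change is mean(m at high levels) −
   mean(m at low levels).
4. **Gene filters and reports.** Probes collapse to genes (max-|FC|
   probe per symbol); genes pass iff q < 0.05 and linear fold change
   > 2; per-group tables are ranked by fold change and optionally
   restricted to GO:0006351 ("transcription, DNA-dependent") for
   transcription-factor candidates.
5. **qPCR validation arithmetic.** 2^−ΔΔCt relative quantification
   against a reference gene and an ES calibrator, and a Mann–Whitney U
   test (exact for small tie-free samples).

QC utilities (sample PCA, correlation heat-map input, bootstrap
hierarchical clustering with Newick export, marker z-score matrices) live
alongside.

## Worked example

Simulate a 15-array experiment (6 ES, 6 OS, 3 CSE) with 50 probes
planted per pattern at log2 effect 4, then run the whole pipeline:

```r
library(otopattern)
cfg <- simulation_config(n_probes = 5000, n_neg_controls = 300,
  planted = setNames(rep(50L, 6),
                     generate_templates("binary6")$templates$name),
  seed = 42)
sim <- simulate_experiment(cfg)
res <- run_pipeline(sim$scans, sim$sheet, bg_method = "subtract_floor")
gt  <- gene_level_filter(res$assignments, sim$annotation)
gc  <- group_counts(res$assignments, gt)
gc$table
```

```
            group probe_count gene_count
1        CSE high          57         50
2 ES and CSE high          54         50
3  ES and OS high          54         50
4         ES high          55         50
5 OS and CSE high          51         50
6         OS high          57         50
```

The six probe counts sum to the number of significant assignable probes
(328 here) — the same partition identity the pattern groups satisfy by
construction. Each group's gene table recovers exactly the 50 planted
genes; the extra probes per group are null probes that crossed the
q < 0.1 line and were assigned to their best-correlated template. Scoring
against the planted truth:

```r
rec <- recovery_report(sim$truth, res$assignments)
rec$overall_recovery   # 1
rec$null_fp_rate       # 0.0066
top_genes(gt[["OS high"]], n = 5)
```

```
  gene_symbol probe_id            q  log2_fc   group
1  Gene004395 PR004395 3.612185e-10 4.190788 OS high
2  Gene000427 PR000427 5.120700e-10 4.141354 OS high
3  Gene001877 PR001877 3.253158e-11 4.139325 OS high
4  Gene002781 PR002781 2.521369e-11 4.132619 OS high
5  Gene001925 PR001925 4.162025e-11 4.131850 OS high
```

All planted OS-high genes are recovered with fold changes near the
planted log2 effect of 4. `subset_transcription_factors(gt[["OS high"]],
sim$annotation)` then keeps the GO:0006351-annotated subset.

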