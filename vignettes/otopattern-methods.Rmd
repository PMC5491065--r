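---
title: "Pattern classification of three-group microarray transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern classification of three-group microarray transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otopattern)
```

`otopattern` compares three cell populations — embryonic stem cells
(ES), otospheres (OS) and cochlear sensory epithelium (CSE) — on
single-channel expression arrays, and classifies each probe's profile
into one of six "group-high" patterns. This vignette is the package's
account of the statistical procedure, the choices behind it, and what
its synthetic-data tests do and do not demonstrate.

## The preprocessing model

Raw feature intensities are modeled per array as

\[ X = S + B, \qquad S \sim \mathrm{Exp}(\alpha), \quad
   B \sim \mathcal{N}(\mu, \sigma^2), \]

the classic normexp convolution for single-channel arrays: a dedicated
population of negative-control probes measures the background \(B\)
directly, while regular probes add an exponentially distributed true
signal. `background_correct()` fits \((\alpha, \mu, \sigma)\) by the
method of moments — the third central moment of \(X\) is \(2\alpha^3\),
which identifies \(\alpha\); variance and mean then give \(\sigma^2\)
and \(\mu\) — and replaces each intensity by
\(E[S \mid X = x] + \text{offset}\) (the conditional-expectation
transform of `limma::normexp.signal`). The moments fit was chosen over
likelihood-based fits because it is closed-form, fast, and directly
testable by parameter recovery on simulated convolutions; when the
moment system is infeasible (non-positive skewness, or
\(\hat\sigma^2 \le 0\), which happens whenever the signal tail is
heavier than exponential) the array falls back, with a warning, to the
simple estimator \(\max(x - \hat\mu_{\mathrm{nc}}, 0.5) + \text{offset}\)
with \(\hat\mu_{\mathrm{nc}}\) the array's negative-control mean. Both
transforms are strictly increasing, so within-array rank order is never
disturbed. The default offset of 16 damps log-scale variance at low
intensities; both method and offset are arguments, and the fallback is
an expected, logged event rather than an error because downstream
pattern classification depends on ranks and contrasts, not on the exact
background functional form.

Quantile normalization (`quantile_normalize()`, via
`limma::normalizeQuantiles` with tie averaging) then forces all arrays
onto a single empirical distribution. On tie-free data the column-wise
multisets of values are *exactly* equal afterwards — a property the
tests assert as identity, not within tolerance. Tied values (in
practice: intensities floored at zero) share the mean reference value
of their tied ranks, which trades exact multiset equality for
order-preservation; this is the standard convention.

Probe filtering happens after normalization, on the linear scale: per
array, the 95th percentile of the negative-control values is computed
by linear interpolation between order statistics (the convention that
interpolates at position \(1 + (n-1)p\); "95th percentile" is otherwise
convention-dependent, so the package fixes and documents one), and a
probe is kept iff its value is at least `brightness_factor` (default
1.10, i.e. "10% brighter") times that threshold on at least
`min_arrays` (default 3) arrays. The comparison is `>=` at the
boundary. Filtering is monotone in both parameters — raising either can
only shrink the kept set — and this is tested on randomized fixtures.

## Per-probe inference and template matching

On log2 values, each probe gets a classical one-way fixed-effects ANOVA
across the three groups, computed vectorized in closed form
(\(F = \frac{SSB/(k-1)}{SSW/(n-k)}\)) and checked against independent
per-probe recomputation. Degenerate probes are handled by convention:
\(SSB = 0\) gives \(F = 0, p = 1\); \(SSW = 0\) with \(SSB > 0\) gives
\(p = 0\). Benjamini–Hochberg q-values are computed across all tested
probes; the probe-level significance threshold defaults to
\(q < 0.1\) and the gene-level filter to \(q < 0.05\) with linear fold
change \(> 2\) — both exposed as arguments, since the two stages of the
analysis legitimately use different stringencies.

Significant probes are classified by template matching. The candidate
set is either the six non-constant binary vectors over (ES, OS, CSE) —
the default, under which the six pattern groups exactly partition the
significant assignable probes — or the 25 non-constant members of
\(\{0, \tfrac12, 1\}^3\), of which \((\tfrac12,\tfrac12,\tfrac12)\) has
zero variance and is excluded from matching. The probe's mean profile
(technical-duplicate pairs averaged first, then samples within group)
is correlated with every matchable template and assigned to the argmax.
Pearson correlation of length-3 vectors is affine-invariant, so only
the *shape* of the profile matters, not its level or amplitude; it also
means several graded templates are correlation-equivalent (the 24
matchable ternary templates fall into 12 equivalence classes), which is
why the binary set is the default: it is the coarsest set that is
correlation-distinguishable, and complementary patterns (e.g. (1,0,0)
vs (0,1,1)) have opposite correlation signs, making that confusion
impossible. Ties in the argmax (possible only in ternary mode) prefer
binary templates, then the lexicographically smallest level vector.
Constant mean profiles are unassignable and excluded from the groups.

The log2 fold change reported per probe is the mean of group means at
the template's high level minus the mean at the low level (half-level
axes contribute to neither side) — a symmetric definition that matches
"upregulated in the high groups" semantics and reduces to the familiar
two-group contrast for single-group-high patterns. Genes with several
probes collapse to the probe with the largest |fold change|; this
favors the best-responding probe and is logged rather than silent.

## Exploratory QC

`pca_samples()` treats samples as observations (probes centered, not
scaled — scaling would let all-noise probes count as much as
high-signal ones); variance fractions equal the covariance
eigenvalues normalized by the trace. `sample_correlation()` is plain
column-wise Pearson. `bootstrap_cluster()` builds the sample dendrogram
under 1 − correlation distance with average linkage (both
config-exposed) and attaches to each internal node the fraction of
probe-resampled trees containing exactly that node's leaf set —
ordinary bootstrap probabilities, deliberately not the multiscale AU
refinement, which is out of the package's scope. Marker heat-map input
comes from `zscore_matrix()`, standardized with the population
(divide-by-n) standard deviation, the common heat-map convention;
constant rows are zero-filled and flagged.

## qPCR arithmetic

`delta_delta_ct()` implements relative quantification:
\(\Delta Ct = Ct_{\mathrm{gene}} - Ct_{\mathrm{ref}}\) per sample
(technical-replicate Cts averaged first), \(\Delta\Delta Ct\) against
the mean \(\Delta Ct\) of the calibrator group (ES by default), and
\(RQ = 2^{-\Delta\Delta Ct}\). Group summaries default to the geometric
convention \(2^{-\overline{\Delta\Delta Ct}}\), computed as a
difference of group means so the calibrator group's fold is exactly 1
in floating point; the arithmetic mean of RQs is available since
published bar charts do not always state which convention they use, and
the two differ once \(\Delta\Delta Ct\) varies within a group.
`mann_whitney_u()` uses the exact rank-sum distribution for combined
\(n \le 20\) without ties and the tie-corrected normal approximation
otherwise, reporting the smaller of the two one-sided U statistics.

## What the synthetic generator emulates

`simulation_config()` defaults describe a 15-array design — ES:6
(standing in for two newly hybridized arrays plus four public ones),
OS:6, CSE:3 — with 60,000 regular probes and 1,000 negative controls,
100 probes planted per binary pattern at log2 effect 4 and biological
noise sd 0.25, a baseline of log2 = 8 for expressed probes, and raw
intensities built exactly as the preprocessing model assumes:
\(2^{\log_2 \text{expression}} + \mathcal{N}(50, 10^2)\) background,
negative controls background-only, everything floored at 0. Ten
percent of null probes are unexpressed (background-only) to exercise
the filter, and ten percent of probes carry the GO:0006351 flag so the
transcription-factor path is testable. Technical-duplicate pairs share
one biological draw and differ by an extra
\(\mathcal{N}(0, \text{noise}/2)\) term. Effect size 4 with noise 0.25
represents a strongly separated experiment; the monotonicity test runs
a 3-point effect grid (0.5, 1.5, 4) to confirm recovery degrades
gracefully.

What this does *not* emulate: probe-sequence and GC effects, spatial
artifacts, intensity-dependent (rather than additive) noise,
correlated probe families, or the heavy, skewed tail of real
expression distributions (planted log2 values are near-symmetric, so
the moments-based normexp fit typically falls back on simulated full
experiments — by design, the dedicated parameter-recovery test draws
from the exponential model itself). Passing recovery tests therefore
demonstrate the pipeline's correctness and its behavior under the
stated noise model, not its performance on any particular real
dataset.

## Problem sizes and determinism

The test suite runs module tests on matrices of a few hundred to a few
thousand probes, and one full-size default experiment (60,000 × 15)
end to end; oracle-equivalence checks use 10,000 random instances per
statistic (BH step-up, one-way ANOVA, template argmax, exact
Mann–Whitney) against brute-force reimplementations written from the
definitions. All generator output is a pure function of the seed —
the same configuration writes byte-identical files — and the bootstrap
clustering is seeded the same way.

## Known limitations

* Group labels are fixed to the (ES, OS, CSE) axis; other three-group
  designs work by aliasing labels, but the package does not generalize
  to \(k \ne 3\) groups (templates and fold-change semantics are
  specifically three-axis).
* In ternary mode, probes matched to graded templates keep graded
  labels and are reported separately; the package deliberately does not
  guess a rule for folding them into the six binary groups.
* The ANOVA treats all arrays as independent observations; technical
  duplicates only affect the mean profiles used for matching. With
  heavy technical replication a mixed model would be more appropriate
  than the fixed-effects layout implemented here.
* GO annotation is always a supplied table; the package never queries
  annotation services, so transcription-factor subsets are only as
  current as the table provided.
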