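Package: otopattern
Title: Template-Matching Expression-Pattern Analysis for Three-Group
    Single-Channel Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparing otic-sphere (otosphere),
    cochlear sensory epithelium and embryonic stem cell transcriptomes on
    single-channel microarrays: normexp background correction, quantile
    normalization, negative-control based probe filtering, per-probe one-way
    ANOVA with Benjamini-Hochberg false discovery rate control, Pearson
    template matching of per-group mean profiles into six "group-high"
    expression patterns, fold-change and q-value gene filters, transcription
    factor subsetting by GO annotation, exploratory quality control (PCA,
    sample correlation, bootstrap hierarchical clustering, marker z-scores),
    and 2^-ddCt qPCR validation arithmetic. Ships a synthetic-data generator
    with planted truth so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
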