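Package: spotscape
Title: Downstream Statistics for Deconvolved Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical toolkit for the analysis layer that sits on top of
    spot-based spatial transcriptomics data after cell-type deconvolution.
    Provides spatial-lag autocorrelation gene filtering, cross-sample core
    marker signatures via Jaccard similarity and hierarchical grouping,
    bootstrap cell-type colocalization with percentile confidence intervals,
    per-spot cell-type diversity entropy, permutation-based region
    enrichment and depletion scores, joint cell-state scores, tertiary
    lymphoid structure (TLS) scoring with ordinary-least-squares gene
    signature extraction and cross-dataset prediction, and spot-wise
    pathway enrichment with two-sided Fisher's exact tests. Includes a
    synthetic data generator with planted ground truth for validating
    every stage, and an end-to-end pipeline runner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
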