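Package: dynfc
Title: Temporal Graph Metrics for Sliding-Window Dynamic Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resting-state dynamic functional-connectivity analysis of
    region-of-interest (ROI) BOLD time series. Builds multi-layer dynamic
    networks by sliding-window Pearson correlation, binarizes layers at a grid
    of sparsity thresholds, and computes spatio-temporal network metrics at
    global and nodal levels: temporal variability of connectivity profiles,
    the temporal correlation coefficient (temporal clustering), and
    time-respecting temporal path lengths (temporal efficiency). Includes
    group-level inference (ANCOVA with site and nuisance covariates,
    repeated-measures profiles over sparsity, partial Spearman correlations
    with clinical scores, Benjamini-Hochberg FDR, subgroup contrasts), a
    hidden-Markov covariance-switching cohort simulator for parameter-recovery
    testing, and an end-to-end pipeline with deterministic seeding.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
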