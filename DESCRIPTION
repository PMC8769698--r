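Package: csdebench
Title: Semi-Simulation and Benchmarking of Cell Type-Specific Differential
    Expression from Bulk Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how reliably cell type-specific differentially
    expressed genes (csDEGs) can be recovered from bulk expression data when
    cell type proportions are known. Provides a semi-simulation engine that
    builds bulk mixtures E = S * C from per-sample cell type-specific
    expression profiles with controlled heterogeneity, injected csDEGs,
    outlier samples and unknown-cell noise; per-gene expression deconvolution
    cores (ordinary, non-negative and Huber-robust least squares); csDEG
    detectors (a group-label permutation recipe, a Welch t-test on group-wise
    deconvolved profiles, and a proportion-by-group interaction model);
    residual-based reliability diagnostics with guidance bands; and
    experiment runners that score detectors against a Wilcoxon-based gold
    standard computed from the known profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
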