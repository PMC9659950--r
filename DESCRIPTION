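Package: rehoflow
Title: Regional Homogeneity and Seed-Based Connectivity Analysis of
    Resting-State BOLD Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end resting-state fMRI group analysis for two-group
    cohort studies: voxelwise regional homogeneity (Kendall's coefficient
    of concordance over 27-voxel neighbourhoods), seed-based functional
    connectivity with Fisher r-to-z maps, Gaussian-random-field
    cluster-level inference on voxelwise two-sample t-maps, and a
    leave-one-out cross-validated logistic-regression classifier with
    permutation validation. Includes the standard functional
    preprocessing chain (volume discard, framewise-displacement QC,
    Friston-24 plus tissue-signal nuisance regression, ideal band-pass
    filtering, Gaussian smoothing), clinical statistics (power analysis,
    normality and group tests, Bonferroni adjustment, apnea-hypopnea
    scoring from respiratory traces), and a synthetic BOLD cohort
    generator with planted local-synchrony and seed-coupling effects so
    every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    glmnet,
    jsonlite,
    nortest,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
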