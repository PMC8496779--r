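Package: metabomr
Title: Metabolome-Wide Matched Case-Control Risk Scans and Two-Sample
    Mendelian Randomisation Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for prospective metabolome-wide association analysis of
    1:1 matched case-control studies and for profiling the influence of an
    exposure (such as body mass index) on the blood metabolome by two-sample
    Mendelian randomisation.  Includes quality control for targeted and
    untargeted metabolomics panels (limit-based imputation, sparsity
    exclusion, median rescaling, derived ratios, log z-scoring), conditional
    logistic regression for matched pairs with stratified heterogeneity
    tests, multiple-testing correction via the effective number of tests,
    inverse-variance weighted, MR-Egger and weighted-median estimators with
    allele harmonisation and instrument pruning, an instrument-specificity
    (variance-explained) screen, effect-profile correlation with a
    negative-control exposure workflow, and a synthetic cohort and GWAS
    summary-statistics generator reproducing the statistical structure the
    analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
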