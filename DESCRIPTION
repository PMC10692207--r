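Package: sleepsig
Title: Task and Resting-State Neural Signatures of Sleep, Depression, and
    Cognition in Synthetic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates population-scale neuroimaging cohorts with planted
    sleep, depression, and cognition effects, and analyses them with the
    matching multi-stage pipeline: covariate-adjusted partial correlations
    among phenotypes, region-wise face/shape decoding of block-design task
    fMRI with a linear support vector machine, representational
    dissimilarity matrices and second-order (representational)
    connectivity, second-level ordinary least squares association maps
    with false discovery rate and Bonferroni control, edge-wise
    resting-state connectivity models, spatial spin-test permutation nulls
    for correlations between neural signature maps, stratified re-analysis
    by depression score and sleep duration, brain-wide and network-wise
    mean connectivity contrasts, and connectome-based predictive
    modelling with cross-validated edge selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
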