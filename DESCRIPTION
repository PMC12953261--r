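Package: depscreen
Title: Sequential Multimodal Depression Screening Models with Certainty
    Stratification and Biomarker Subtyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating multimodal depression-screening
    classifiers on tabular primary-care cohorts: a calibrated synthetic cohort
    generator (questionnaire items and totals, blood biomarkers, heart-rate
    variability, anthropometrics, biographic variables), fold-safe
    preprocessing (rare-category aggregation, k-nearest-neighbour imputation,
    Yeo-Johnson transformation), Boruta shadow-feature and greedy forward
    feature selection, gradient-boosted and PCA-SVM base-model pipelines,
    nested cross-validated evaluation against a PHQ-9 cutoff baseline, stacked
    and sequential models with propagation thresholds and traffic-light
    certainty bands, and Gaussian-mixture subtyping of the depressed group
    with a post-hoc comparison battery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
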