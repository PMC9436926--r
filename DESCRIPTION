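Package: bftrans
Title: Basal Forebrain Microstructure and Imaging Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying the cholinergic basal forebrain in
    early psychosis: clinical-stage statistics (case-control microstructure
    differences, structure-MRS coupling and its decoupling in patients,
    clinical and cognitive correlates), seed-based structural covariance
    mapping of quantitative T1, atlas-style expression preprocessing with
    coordinate-based sample-to-vertex matching, region-specific expression via
    empirical-Bayes moderated t-statistics, gene-wise random-intercept mixed
    models linking covariance maps to expression, and disease / cell-type
    (pSI) enrichment. A synthetic-data generator with the same statistical
    structure as the study design drives end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    car,
    limma,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
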