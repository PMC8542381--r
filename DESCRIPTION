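Package: pneumoscore
Title: External Validation of Pediatric Pneumonia Mortality Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements three published point-based clinical prediction rules
    for in-hospital mortality among children hospitalized with pneumonia -- the
    Respiratory Index of Severity in Children (RISC) score for HIV-negative
    children, the RISC-Malawi score using weight-for-age z-scores, and an
    adapted PERCH score -- together with a complete external-validation
    pipeline: complete-case eligibility filtering, case-fatality ratios with
    Clopper-Pearson exact confidence intervals, cut-point test characteristics
    (sensitivity, specificity, likelihood ratios), ROC curves and AUC with
    qualitative discrimination bands, and risk predictiveness curves. A seeded
    synthetic cohort generator calibrated to published sign prevalences and
    per-stratum case-fatality ratios allows the whole pipeline to be exercised
    end-to-end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
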