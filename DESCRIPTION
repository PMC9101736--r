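Package: leamq
Title: Scoring and Clinical Validation of the LEAM-Q Low Energy
    Availability Screening Questionnaire
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening male athletes for low energy availability
    (LEA) with the LEAM-Q questionnaire and a panel of clinical markers.
    Provides key-driven scoring of questionnaire responses into section and
    composite scores, derivation of clinical quantities (Weir energy
    expenditure, Cunningham predicted resting metabolic rate and the RMR
    ratio, Vermeulen free testosterone), threshold-based clinical indicator
    profiles with a composite LEA case/control/excluded classification, and
    the full validation pipeline: test-retest intraclass correlation with
    unreliable-item removal, a covariate-adjusted association screen, ROC
    analysis with Youden-index threshold selection and a minimum-sensitivity
    retention rule, and case-control comparisons. A calibrated synthetic
    multi-centre cohort generator makes every pipeline stage testable
    without access to athlete data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
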