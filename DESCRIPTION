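Package: mcdsl
Title: Causal Risk-Factor Discovery for Stage-3 Acute Kidney Injury Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building matched case-control cohorts of stage-3 acute
    kidney injury from longitudinal serum-creatinine records using KDIGO
    staging, encoding categorical clinical features at a pre-onset checkpoint,
    and discovering direct causal risk factors with a two-phase procedure:
    Markov-blanket dimensionality reduction by chi-square
    conditional-independence testing, followed by many-to-one causal direction
    learning with a discrete additive-noise model fitted on a joint-state
    converted feature. Discovered cause combinations are verified by odds
    ratios with 95 percent confidence intervals, and their predictive value is
    quantified by stratified k-fold cross-validation over five classifiers.
    A synthetic EHR-style cohort generator with planted causal structure
    supports end-to-end validation without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    FNN,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
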