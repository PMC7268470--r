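Package: coldRR
Title: Cold-Deck Imputation of Health Behaviours with
    Misclassification-Corrected Relative Risks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Augments cancer-registry-style cohorts with fully imputed
    binary health behaviours drawn from an unrelated survey-style donor
    dataset using stratified random cold-deck imputation.  Each case
    receives two independently drawn donor values; their agreement beyond
    chance (phi coefficient) calibrates the information content of the
    imputation, and a closed-form correction inverts the attenuation of
    the relative risk of one-year mortality caused by exposure
    misclassification.  Includes crude and Cochran-Mantel-Haenszel
    age-adjusted risk ratios, a repetition engine with empirical
    percentile intervals and impossibility accounting, and a survival
    simulator for validating the estimator at known target relative
    risks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
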