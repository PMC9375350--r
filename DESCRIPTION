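Package: cariesrecall
Title: Risk-Based Dental Recall Intervals from Longitudinal Caries Increment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal dental caries increment analysis on
    surface-level modified ICDAS II examination data. Classifies every tooth
    surface's change between baseline and follow-up into progression,
    regression, or neither under two diagnostic cutoffs (cavitated 3-6,
    cavitated plus non-cavitated A-6), computes the child-level adjusted
    caries increment (ADJCI), compares mean increments across follow-ups
    within caries-risk strata by repeated-measures ANOVA with Bonferroni
    post hoc tests, pools hot-deck multiply-imputed increments with Rubin's
    rules, and converts the pattern of significant increments into
    risk-stratified recall-interval recommendations. Includes a synthetic
    cohort generator calibrated to published school-cohort surface-state
    distributions and attrition patterns, so the whole pipeline is testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
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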