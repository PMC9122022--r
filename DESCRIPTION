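Package: oaphen
Title: Validation of Knee Osteoarthritis Case-Identification Algorithms in
    Coded Primary-Care Records
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for developing and validating electronic-health-record
    case-identification (phenotyping) algorithms for knee osteoarthritis in
    longitudinal coded primary-care data. Provides eligibility and exclusion
    filtering of Read-coded event histories, a declarative temporal rule
    engine (code counts, time windows, minimum separations, imaging
    proximity), rule-based gold-standard adjudication from imaging-report
    findings and questionnaire knee-pain data, positive predictive value and
    sensitivity with Wald 95% confidence intervals, a synthetic longitudinal
    cohort generator, and an end-to-end pipeline with a reproduction mode
    for the published validation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
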