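Package: oicera
Title: Opioid-Induced Constipation Risk Analysis for Claims Data
Version: 0.1.0
Authors@R:
    person("OIC", "Pipeline Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for studying opioid-induced constipation (OIC)
    in administrative claims data: builds continuous drug-exposure eras from
    pharmacy fills and inpatient administrations with stockpile chaining and
    gap bridging, assembles a new-user elderly cohort with washout, continuity
    and cancer exclusions, ascertains a composite constipation outcome
    (diagnosis, new/changed laxative, procedure) during opioid exposure,
    engineers baseline covariates over the pre-index year, multiply imputes
    missing laboratory averages by predictive mean matching, and estimates
    adjusted hazard ratios by Cox regression with Rubin pooling. Ships a
    synthetic claims generator with a known proportional-hazards truth so the
    whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    survival (>= 3.4),
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
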