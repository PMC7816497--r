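Package: rptcs
Title: Conditional Survival Analysis for Resected Primary Retroperitoneal Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic (conditional) survival analysis for registry cohorts of
    surgically resected primary retroperitoneal tumors. Provides Kaplan-Meier
    estimation of overall and cause-specific survival with Greenwood variance,
    kernel-smoothed hazard curves, log-rank comparisons, univariable and
    multivariable Cox proportional-hazards modelling, the three-year
    conditional survival statistics COS3 and CCSS3 with their conditional
    survival matrices, and standardized-difference comparisons between
    prognostic subgroups. A seeded generator of SEER-like synthetic cohorts
    with competing causes of death makes the whole pipeline testable without
    a registry extract.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
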