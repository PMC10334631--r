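Package: mwascreen
Title: Medication-Wide Association Screening of Longitudinal Claims Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for medication-wide association studies
    (MWAS) on longitudinal health-insurance claims: builds a
    cancer-prognosis cohort with a washout period and treatment-based
    time zero, classifies per-drug exposure under a past-one-year
    incident-user design at ATC levels 2 and 4, screens every drug for
    association with all-cause and cause-specific mortality using
    covariate-adjusted Cox proportional-hazards models under a two-stage
    discovery/validation scheme with Benjamini-Hochberg false discovery
    rate control, and reports volcano-style summaries. Includes a
    synthetic claims generator with planted drug effects so that every
    stage of the screen can be verified against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    ggplot2,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
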