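Package: mpeblock
Title: Sensory Nerve Block Kinetics from Thermal-Latency Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the duration and intensity of peripheral sensory
    nerve blocks in rodent thermal-latency assays (plantar test,
    tail-flick test). Implements percent-maximal-possible-effect (%MPE)
    scoring with censoring at the assay cut-off, baseline trimming and
    cohort inclusion filters for diabetic peripheral-neuropathy
    phenotyping, balanced incomplete block measurement scheduling on a
    1.5-minute slot grid, cubic-polynomial block-kinetics estimation with
    onset/release landmark extraction and threshold-based duration
    estimation, ROC/AUC discrimination between anesthetic treatments and
    neuropathy conditions with trapezoidal areas and chi-squared area
    contrasts, summary-statistic t-tests, and a seeded synthetic
    cohort/trajectory generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
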