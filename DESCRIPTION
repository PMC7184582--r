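Package: perioprp
Title: Periodontitis Case Definitions and Partial-Mouth Recording Protocol Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule engines for the 2012 CDC/AAP and 2018 EFP/AAP periodontitis
    case definitions, the five named full-mouth partial recording protocols
    (Ramfjord teeth, CPITN teeth, MB-B, MB-B-DB, MB-B-DL), and the complete
    diagnostic-performance battery for comparing partial-protocol diagnoses
    against the full-mouth reference: sensitivity, specificity, accuracy,
    precision, Youden's index, F1, Matthews correlation, diagnostic odds
    ratio with log-scale confidence intervals, binary hard-label ROC/AUC and
    Hand-Till multiclass AUC, per-stage precision, and the staging
    reclassification cross-tabulation. Includes a calibrated synthetic
    generator of NHANES-like full-mouth periodontal charts so the whole
    pipeline is testable without survey data, long-format CSV chart
    interchange with a Universal-numbering dialect, and an end-to-end
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
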