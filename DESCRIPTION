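Package: ftduse
Title: Evaluation of Potentially Inappropriate Transdermal Fentanyl Use in
    Prescription Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying potentially inappropriate use of fentanyl
    transdermal patches (FTD) in non-cancer outpatients from prescription
    claims tables. Standardizes opioid doses to morphine milligram
    equivalents (MME) and interval-based estimated MME per day (eMME/day),
    applies a five-criterion rule engine (prescription period, dose,
    per-prescription and annual overlap, multi-institution use) stratified
    by age and prescription frequency, summarizes utilization trends
    (rates per 100,000 registrants, annual percent change), and assesses
    inequality of use with classic and modified Lorenz curves and Gini
    coefficients. Includes a synthetic claims generator that plants
    criterion violations with ground-truth labels so every pipeline stage
    is testable without access to national claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
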