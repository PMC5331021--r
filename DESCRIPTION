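Package: actiphase
Title: Actigraphy Feature Extraction and Discriminant Classification of
    Bipolar Illness Phase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing minute-epoch wrist-actigraphy recordings from
    psychiatric inpatients. Extracts 64-minute continuous active morning and
    evening periods using a zero-run relaxation search, computes six linear and
    non-linear activity parameters (mean counts per minute, relative standard
    deviation, RMSSD, lag-1 autocorrelation, sample entropy, and a high/low
    frequency Fourier variance ratio), and classifies illness phase (mania,
    bipolar depression, mixed state) by canonical discriminant function
    analysis with leave-one-out cross-validation and stratified case bootstrap.
    Includes a calibrated synthetic-cohort generator so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
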