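Package: compcal
Title: Post-Measurement Compressed Calibration for ICP-MS Survey Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers element concentrations, with propagated standard
    deviations, from ICP-MS survey-scan intensities using only the external
    calibration standard dilution series measured in the same run. Fits, per
    mass channel, a linear intensity-versus-dilution-factor model with the
    error variance as an estimated parameter, inverts the fitted relation to
    quantify assay samples (delta-method uncertainty), screens estimates for
    significance and cross-method consistency, and computes leachate
    time-series summaries. Includes a synthetic survey-scan generator with
    known ground truth and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
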