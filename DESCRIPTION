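Package: srmtdm
Title: Targeted LC-MS/MS Quantification and Therapeutic Drug Monitoring of
    Cetuximab
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Scheduled selected-reaction-monitoring (SRM) data analysis for
    stable-isotope-dilution quantification of the anti-EGFR monoclonal
    antibody cetuximab in plasma, from chromatographic peak detection and
    integration of the two surrogate peptides (HT4 and LT3) through weighted
    linear calibration with data-driven weighting selection, EMA-style
    bioanalytical validation statistics (precision, accuracy, matrix effect,
    selectivity, LLOQ qualification, stability, recovery accounting), to
    cohort-level exposure-response analysis of trough concentrations (group
    comparison, empirical ROC threshold discovery, exact 2x2 association).
    A synthetic-data module generates chromatograms, calibration and QC
    batches, and patient cohorts with the statistical structure the analysis
    assumes, so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
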