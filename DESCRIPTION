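Package: tiafit
Title: Reduced Time Point Estimation of Time-Integrated Activity for
    Radiopharmaceutical Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for internal dosimetry time-activity analysis after
    radiopharmaceutical therapy (e.g. 177Lu-DOTATATE peptide receptor
    radionuclide therapy). Fits mono- and biexponential time-activity curves
    with AIC-based model selection, computes analytic time-integrated activity
    (TIA), implements the Hanscheid and Madsen single-time-point estimators,
    enumerates clinical and simulation sampling-schedule grids, simulates
    virtual patient cohorts with truncated lognormal kinetic parameters and a
    power-law activity-dependent measurement-noise model, and quantifies the
    error and variability of every sampling schedule (RMSE, mean percent
    error, mean absolute percent error) to identify minimum-RMSE optimal
    imaging schedules for 1, 2 and 3 time point dosimetry.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
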