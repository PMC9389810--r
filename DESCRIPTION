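Package: cusumgfr
Title: Age-Adjusted CUSUM Monitoring of Longitudinal eGFR for Early
    Detection of Kidney Disease Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Sequential detection of clinically relevant decline in kidney
    function from serial serum-creatinine measurements. Converts creatinine
    to estimated glomerular filtration rate (eGFR) with the 2021 CKD-EPI
    race-free creatinine equation, accumulates standardized downward
    deviations from an age-adjusted normal reference in a one-sided CUSUM
    statistic, and signals patients likely to progress to end-stage kidney
    disease when the statistic crosses a tuned threshold. Includes cohort
    selection rules for building normal and end-stage groups from
    longitudinal electronic-health-record style lab tables, reference
    estimation with a Kolmogorov-Smirnov normality check, k-fold
    cross-validated tuning of the allowance and threshold with ROC
    summaries, earliness and subgroup performance evaluation, and a seeded
    synthetic longitudinal cohort generator so the whole pipeline is
    testable without access to real patient data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
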