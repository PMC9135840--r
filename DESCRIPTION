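Package: renaldaa
Title: Kidney-Function Decline Under Direct-Acting Antiviral Prescription Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A new-user cohort pipeline for assessing decreased kidney function
    in hepatitis C patients prescribed direct-acting antivirals (DAAs), exercised
    on synthetic electronic-health-record data. Implements cohort construction
    with six exclusion criteria and an attrition report, classification into ten
    prescription patterns with a +/-30-day concomitancy window, treatment-episode
    (drug-era) construction with a 28-day gap and 7-day grace period, eGFR
    derivation from serum creatinine via the Japanese GFR equation, KDIGO
    eGFR-category drop outcomes with full censoring logic, and person-time
    incidence-rate ratios versus a control pattern with exact conditional
    inference. A synthetic-data generator with injected ground truth supports
    parameter-recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
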