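Package: ippscreen
Title: Screening Hospital Admissions for Potentially Inappropriate Prescribing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens per-admission electronic health record extracts of older
    hospitalized patients (70 years and over) for potentially inappropriate
    medications (PIMs) and potential prescribing omissions (PPOs) with a
    declarative STOPP/START-style criteria engine over ATC-coded medication
    administrations, coded diagnoses, laboratory results, and risk scores.
    Provides prevalence tabulation, clustered logistic association models
    fitted by generalized estimating equations with robust sandwich variance,
    average predictive comparisons, and adjusted time-trend analyses, plus a
    seeded synthetic cohort generator calibrated to published cohort
    characteristics for end-to-end validation of the whole pipeline.
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
    yaml,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    optparse
Config/testthat/edition: 3
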