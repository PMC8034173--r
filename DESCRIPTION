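Package: rctfragility
Title: Fragility Index and Fragility Quotient for Two-Arm Randomized Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the fragility index (FI) and fragility quotient (FQ) of
    statistically significant dichotomous outcomes from two-arm 1:1
    randomized controlled trials. Provides an exact two-sided Fisher test on
    2x2 contingency tables built on a first-principles hypergeometric
    enumeration, the iterative event-addition algorithm defining the FI,
    cohort-level summaries (median/IQR aggregation with (n+1)-position
    quantile interpolation), CSV/JSON import and export, a built-in cohort of
    six phase-3 hepatocellular-carcinoma trials, and a seeded binomial trial
    simulator for calibration and for studying the FI-p relationship.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
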