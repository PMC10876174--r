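Package: acnscore
Title: Diagnostic Scoring and Outcome Comparison for Pediatric
    Adrenocortical Neoplasms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements four histopathology-based diagnostic
    classification systems for pediatric adrenocortical neoplasms --
    the nine-item Wieneke criteria, the modified five-item microscopic
    score with Ki67 proliferative index, and the reticulin algorithm
    with adult (>5 mitoses/50 HPF) and pediatric (>15 mitoses/20 HPF)
    mitotic cutoffs -- together with the statistical machinery used to
    compare them: contingency tables, Cohen's kappa with asymptotic
    confidence intervals, Cramer's V, Kaplan-Meier estimation, log-rank
    tests, Cox and logistic model comparison by AIC, and a calibrated
    synthetic cohort generator for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
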