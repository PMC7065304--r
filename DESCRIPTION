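Package: mphdose
Title: Individualized Methylphenidate Dosing from Longitudinal Binary
    Response Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits a random-intercept logistic mixed model with a log-dose
    term to longitudinal binary improvement outcomes in children with ADHD
    treated with methylphenidate (MPH), using an adaptive Gauss-Hermite
    approximation to the marginal likelihood. The fitted model is inverted
    per patient to recommend the mg/kg dose that attains a target
    improvement probability, with the patient's random intercept updated by
    empirical Bayes at each follow-up visit. Includes a synthetic-cohort
    generator for longitudinal visit records, eligibility filtering,
    univariable-to-multivariable covariate screening, and dose-response
    curve construction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    ggplot2
Config/testthat/edition: 3
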