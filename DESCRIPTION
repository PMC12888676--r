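Package: biomonpower
Title: Power, Sample Size and Bias Calculators for Biomonitoring-Based
    Epidemiology Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Study-design calculators for epidemiology studies that assess
    exposure with biomarkers measured with classical (additive, independent,
    homoscedastic) error. Implements closed-form arithmetic on between- and
    within-person variance components (intraclass correlation, validity
    coefficient, number of repeated measurements required for a target
    validity, attenuation of linear-regression slopes and the resulting
    percent bias), sample-size and minimum-detectable-effect calculations for
    simple linear regression with an error-prone exposure, and a Monte-Carlo
    engine estimating power and odds-ratio bias for logistic regression when
    the analysed exposure is a person-mean of repeated noisy measurements.
    Ships the parameter sets of two published birth-cohort case studies and a
    report generator, plus a command-line interface for all calculators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    parallel,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
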