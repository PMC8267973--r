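Package: imtgrowth
Title: Logistic Growth Modelling of Carotid Intima-Media Thickness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates a three-parameter logistic growth curve to carotid
    intima-media thickness (IMT) measurements against patient age, computes
    the analytic inflection-point and slope statistics of the fitted curve,
    and derives from them a recommended age window for starting statin
    treatment. Includes a seeded synthetic-cohort generator emulating
    bilateral carotid measurements, goodness-of-fit statistics under both
    root-mean-square-error denominator conventions, group comparison of
    slope profiles, delimited-text data input/output, and a command-line
    front end.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
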