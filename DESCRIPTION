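Package: ovogrowth
Title: Chick Embryo Growth Modeling from Near-Infrared Egg Opacity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-destructive analysis of chick embryonic growth from
    near-infrared (NIR) transmission measurements of incubated eggs.
    Simulates graded egg cohorts and auto-ranging NIR sensor voltage
    traces, computes the egg opacity statistic (LED input current over
    average output voltage), splits cohorts by the midpoint weight rule,
    fits exponential, logistic, power and Gompertz growth curves to
    opacity series by Levenberg-Marquardt non-linear least squares,
    compares models by RMSE and R-squared, and calibrates calculated
    opacity against a reference embryo-weight trajectory to predict
    embryo weight during incubation days 6-16.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    tibble,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
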