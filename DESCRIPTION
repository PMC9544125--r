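Package: pswvar
Title: Asymptotic and Bootstrap Variance Estimation for Propensity Score
    Weighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo evaluation of asymptotic (M-estimation sandwich)
    versus bootstrap standard errors for propensity-score-weighted
    estimates of differences in means, risk differences, and relative
    risks.  Implements four weight families (inverse probability of
    treatment weights targeting the average treatment effect, weights for
    the average treatment effect in the treated, matching weights, and
    overlap weights), a calibrated synthetic super-population generator,
    propensity-score trimming including Crump's optimal threshold,
    covariate balance and effective-sample-size diagnostics, and a
    simulation engine computing standard-error ratios and empirical
    coverage of normal-theory confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
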