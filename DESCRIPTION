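Package: adscreensim
Title: Monte Carlo Microsimulation of Presymptomatic Alzheimer Disease
    Screening and Treatment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-level Monte Carlo microsimulation of presymptomatic
    Alzheimer disease (AD) screen-and-treat strategies. Builds synthetic
    life-history cohorts calibrated to a sex-specific life table and an
    exponential age-specific AD incidence curve, models the AD course with an
    annual-cycle severity-by-location Markov model with published utilities
    and discounting, applies a lead-time-dependent treatment effect with
    harm and discontinuation, classifies individuals with a
    sensitivity/specificity screen against a 20-year conversion horizon, and
    aggregates net quality-adjusted life years (QALYs) per 1000 screened or
    treated over repeated trials with common random numbers. Includes
    one-way, two-way and probabilistic (third-order Monte Carlo) sensitivity
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
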