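Package: trafficpm
Title: Joint Bayesian Meta-Regression of Urban Traffic-Related PM2.5 and
    Health Impact Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of urban fine particulate matter
    (PM2.5) source-apportionment studies. Fits a joint bivariate-normal
    meta-regression of log overall and log traffic-related PM2.5
    concentrations by a conjugate Gibbs sampler with a Wishart prior on
    the residual precision matrix, derives per-city posterior
    concentration distributions and the probability that non-traffic
    PM2.5 exceeds the WHO annual guideline, and propagates Integrated
    Exposure-Response (IER) parameter uncertainty into population
    attributable fractions for a complete-traffic-removal counterfactual.
    Includes a synthetic-data generator emulating the WHO
    source-apportionment database so the full pipeline is testable
    without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    coda
Config/testthat/edition: 3
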