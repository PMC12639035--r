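Package: climladder
Title: Fixed-Effects and Multilevel Bayesian Models for Climate-Driven
    Conflict Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ladder of models for regional longitudinal panels of
    conflict-event counts driven by climate anomalies: Gaussian
    fixed-effects regression with Conley/Newey-West spatial-temporal HAC
    standard errors, fixed-effects negative binomial GLMs, and multilevel
    Bayesian negative binomial models that partially pool region
    coefficients through a multivariate normal distribution with
    group-mean (within-between) correction and pool period effects
    through a climate-forcing level model. Includes residual diagnostics,
    PSIS-LOO ELPD model comparison, posterior predictive checks,
    climate-scenario projections with full uncertainty propagation, and a
    synthetic panel generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    coda,
    jsonlite,
    rjags,
    stats,
    utils
Suggests:
    geosphere,
    sandwich,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
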