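Package: sleepcoda
Title: Bayesian Multilevel Compositional Data Analysis of Sleep
    Architecture and Morning Affect
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing nightly sleep architecture (wake in bed,
    light sleep, slow-wave sleep, REM) as a multilevel composition and
    relating it to next-morning affect. Provides isometric log-ratio
    coordinates built from sequential binary partitions, between-/
    within-person decomposition of repeated compositions, Bayesian
    multilevel Gaussian models with correlated random slopes fitted by
    Gibbs sampling through JAGS, Pareto-smoothed importance-sampling
    leave-one-out cross-validation with Bayesian stacking for model
    comparison, posterior compositional substitution (time-reallocation)
    analysis, and a calibrated synthetic-data generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
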