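Package: bnpgrowth
Title: Bayesian Non-Parametric Growth Curve Modeling with Dirichlet
    Process Mixture Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits linear latent growth curve models in which the
    measurement-error distribution is left unspecified and modeled by a
    Dirichlet process mixture of multivariate normals via a truncated
    stick-breaking Gibbs sampler. Provides closed-form Dirichlet process
    results (posterior base-measure mixing, the asymptotic Poisson law of
    the number of occupied clusters, and the exact two-gamma posterior of
    the precision parameter with its augmented-variable sampler), Geweke
    convergence diagnostics and highest-posterior-density intervals, a
    seeded generator for clean and outlier-contaminated longitudinal
    panels, and a simulation-study harness that aggregates bias, standard
    errors, mean squared error, coverage, and convergence rates across
    precision-parameter priors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    coda,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
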