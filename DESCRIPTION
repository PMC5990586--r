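Package: pvlreg
Title: Bayesian Regression for Parameters of the PVL-Delta Model of the Iowa Gambling Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian regression framework for testing relationships
    between cognitive-model parameters and continuous covariates with Bayes factors,
    instantiated for the Prospect Valence Learning model with delta learning rule
    (PVL-Delta) applied to the Iowa Gambling Task. Provides the task payoff schedule
    and a forward agent simulator, probit-scale hierarchical model specifications
    (intercept-only, Jeffreys-Zellner-Siow mixture-of-g regression, and a
    median-split comparison model), a conjugate Gibbs / adaptive Metropolis sampler,
    Savage-Dickey density-ratio Bayes factors with a log-spline-type posterior
    density estimator, an analytic one-dimensional-integral JZS linear-regression
    Bayes factor used as an independent oracle, and a simulation-study harness that
    quantifies the bias introduced by dichotomizing continuous covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    mgcv,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    coda,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
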