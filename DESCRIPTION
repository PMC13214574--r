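Package: braintraj
Title: Stochastic Dynamical Modelling of Adult Brain-Structure Volume
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-time stochastic linear dynamical modelling of adult
    brain-structure volumes measured longitudinally with MRI. The latent state
    of each individual couples the true (noise- and site-free) volume of a
    structure with its change rate; age-dependent acceleration bias and process
    noise are parameterized by natural cubic splines, measurements carry
    additive site bias and site-specific Gaussian noise, and the initial
    distribution at age 18 depends linearly on sex and intracranial volume.
    Provides exact zero-order-hold discretization via the Van Loan augmented
    matrix exponential, Kalman-filter marginal likelihoods and
    Rauch-Tung-Striebel smoothing per subject, Bayesian fitting (MAP by L-BFGS
    followed by No-U-Turn sampling), closed-form autocovariance and
    autocorrelation curves, explained-variance decompositions of volume
    variation into stable young-adult level versus accumulated change,
    correlations of single-volume, delta and least-squares slope estimators
    with the latent change rate, population norm curves, analytic study-design
    power for slope estimation, and a multi-site synthetic cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
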