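Package: abcpa
Title: Likelihood-Free Inference and Model Selection by Population Annealing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Approximate Bayesian computation (ABC) with population annealing
    for parameter inference and Bayes-factor model selection in dynamic models
    of biochemical networks. A weighted particle ensemble is annealed through a
    decreasing sequence of ABC tolerances by reweighting with the indicator
    kernel, ABC-MCMC rejuvenation and effective-sample-size triggered
    multinomial resampling; survival fractions recorded at resampling events
    yield an estimate of the ABC marginal likelihood, so two models fitted to
    the same data give a Bayes factor. Includes an ABC rejection-sampler
    baseline, posterior-parameter-ensemble trajectory simulation with weighted
    quantile bands, a vectorized fixed-step Runge-Kutta integrator for the
    coherent and incoherent feed-forward-loop network-motif models, and a
    generator of artificial observed data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
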