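Package: evppi
Title: Fast Estimation of the Expected Value of Partial Perfect Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the expected value of perfect and partial perfect
    information (EVPI/EVPPI) from probabilistic sensitivity analysis samples
    of health-economic decision models. Provides Monte Carlo reference
    estimators (nested and single-loop), non-parametric regression of net
    benefits on focal parameters via dense Gaussian-process regression with
    a squared-exponential kernel, and a fast two-dimensional route that
    projects the focal parameters with principal fitted components and fits
    a Matern field by its stochastic partial differential equation
    representation on a finite-element mesh, as a latent Gaussian model with
    empirical-Bayes Laplace inference. Includes synthetic decision models
    with analytic conditional-expectation oracles, residual and
    monotonicity diagnostics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
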