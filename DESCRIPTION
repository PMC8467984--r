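Package: lvjump
Title: Stationary Responses of Predator-Prey Models under Gaussian and
    Poisson White Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic averaging of Lotka-Volterra type predator-prey
    models (predator saturation and predator competition variants)
    driven by combined Gaussian and Poisson white noise. Computes the
    averaged generalized Fokker-Planck-Kolmogorov coefficients on the
    level sets of the Lotka-Volterra first integral, solves the
    stationary equation by a second-order perturbation scheme, and maps
    the result to joint and marginal population-density distributions,
    moments, relative fluctuations and L2 discrepancy metrics. A
    jump-diffusion Monte Carlo simulator is included for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
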