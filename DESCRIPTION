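Package: shashnorm
Title: Non-Gaussian Normative Modelling with Sinh-Arcsinh Hierarchical
    Bayesian Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Normative (growth-chart style) modelling of phenotypes with
    skewed and kurtotic residual distributions, collected across multiple
    acquisition sites.  Implements the sinh-arcsinh (SHASH) distribution
    family, including a moment-standardised reparameterisation (SHASH_b)
    whose location and scale parameters are exactly the distribution mean
    and standard deviation, hierarchical Bayesian regression with
    site-specific random intercepts, No-U-Turn MCMC sampling and MAP
    estimation, deviation (z-) scores, centile curves, convergence
    diagnostics, goodness-of-fit statistics, and a multi-site cohort
    simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
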