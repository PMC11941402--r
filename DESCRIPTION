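Package: lamlbias
Title: Bias Diagnostics for Laplace-Approximated Marginal Likelihoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the parameter-dependent bias of the Laplace
    approximation to the marginal likelihood (LAML) of hierarchical models.
    Implements six latent-covariate model families (errors-in-variables
    regression with normal, Poisson, logit and probit responses, a
    non-identifiable Poisson model with quadratic mean, and a variance
    partition model), gold-standard marginal likelihoods by adaptive
    quadrature and simple Monte Carlo, the Laplace approximation with inner
    Newton optimisation and Hessian correction, Geyer-Thompson importance
    ratio likelihoods, data-cloning maximum likelihood with an
    identifiability diagnostic, per-observation bias factors computed exactly
    and by MCMC plus kernel density estimation, and simulation drivers for
    likelihood-curve, profile-likelihood and confidence-interval coverage
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    coda,
    statmod,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    numDeriv,
    mvtnorm
Config/testthat/edition: 3
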