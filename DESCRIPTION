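Package: jsdmprobit
Title: Joint Species Distribution Modelling by Bayesian Multivariate Probit Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits joint species distribution models (JSDMs) to site-by-taxon
    presence/absence survey data using Bayesian multivariate probit regression.
    Each taxon's abiotic niche is a probit regression on environmental
    covariates, and a between-taxa residual correlation matrix captures
    co-occurrence not explained by the environment, a proxy for biotic
    interaction. Fitting uses a Gibbs sampler with truncated-normal
    latent-variable augmentation and a parameter-expanded correlation update.
    The surrounding workflow includes forward stepwise AIC covariate selection
    with forced survey-design terms, four nested model variants (null,
    community-only, environment-only, full), deviance and DIC model comparison
    via the GHK orthant-probability simulator, posterior effect-size and
    correlation-network summaries, co-occurrence dendrograms, Moran's I and
    bootstrap spline-correlogram residual diagnostics, and a generator for
    survey-structured synthetic communities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    ape,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
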