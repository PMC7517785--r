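Package: lgcdm
Title: Latent Growth Cognitive Diagnostic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits reparameterized DINA (RDINA) cognitive diagnostic models whose
    attribute-mastery logits follow a latent growth curve over repeated measurement
    occasions, with optional person-level covariates such as intervention indicators.
    Provides marginal maximum-likelihood and posterior-mode estimation by EM with
    quasi-Newton polishing over Gauss-Hermite quadrature, posterior attribute
    classification with proportion-correct and lambda statistics, local
    identification diagnostics, data generators for longitudinal diagnostic
    designs, and a Monte-Carlo parameter-recovery and model cross-fitting harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    statmod,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
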