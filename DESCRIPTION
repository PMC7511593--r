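Package: modmedsem
Title: Estimators for Second-Stage Moderated Mediation with Latent Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the interaction between a latent mediator
    and a latent moderator is estimated in second-stage moderated mediation
    models. Provides a population data generator with configurable indicator
    reliability and error distributions, four estimators (composite-score path
    analysis, constrained and unconstrained product-indicator structural
    equation models, and latent moderated structural equations fitted by
    adaptive Gauss-Hermite marginal maximum likelihood with robust sandwich
    standard errors), case-resampling bootstrap inference, Johnson-Neyman
    probing of simple slopes, and Monte-Carlo evaluation metrics (relative
    bias, standard-error ratio, coverage, power/type-I error and completion
    rate) for factorial simulation designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
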