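Package: qgscales
Title: Quantitative Genetic Parameters on the Data Scales from GLMMs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts latent-scale parameters of generalized linear mixed
    models (intercept, fixed-effect predictions, additive genetic and other
    variance components) into quantitative genetic parameters on the expected
    and observed data scales: population means, phenotypic variances, additive
    genetic variance via the average inverse-link derivative (Psi),
    heritabilities, evolvability and the multivariate G matrix. Exact analytic
    fast paths are provided for the Poisson/log model and the binomial/probit
    threshold (liability) model. Also predicts the evolutionary response to
    selection through the latent scale, includes a forward simulator of
    truncation selection on count traits for validating those predictions, and
    applies any computation across posterior samples with mode and
    highest-posterior-density summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
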