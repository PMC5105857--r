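# Shared fixtures: small models used across test files.

pois_half <- function(predicted = NULL) {
  latent_model(mu = 0, var_a = 0.5, var_o = 0, family = "poisson.log",
               predicted = predicted)
}

probit_unit <- function(var_a = 1, var_re = 0, var_o = 0, mu = 0,
                        predicted = NULL) {
  latent_model(mu = mu, var_a = var_a, var_re = var_re, var_o = var_o,
               family = "binomial.probit", predicted = predicted)
}

# Independent high-resolution quadrature oracle (trapezoid over +/- 12 sd),
# deliberately not Gauss-Hermite so it cannot share errors with the package.
trapz_expectation <- function(f, mean, variance, n = 20001) {
  s <- sqrt(variance)
  l <- seq(mean - 12 * s, mean + 12 * s, length.out = n)
  y <- f(l) * stats::dnorm(l, mean, s)
  sum((y[-1] + y[-n]) / 2 * diff(l))
}
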