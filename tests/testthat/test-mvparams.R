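two_pois <- function(g12 = 0.2, predicted = NULL) {
  mv_latent_model(mu = c(0, 0),
                  G = matrix(c(0.5, g12, g12, 0.5), 2),
                  P = matrix(0, 2, 2),
                  families = c("poisson.log", "poisson.log"),
                  predicted = predicted)
}

test_that("identity links reduce the multivariate case to matrix sums", {
  G <- matrix(c(0.4, 0.1, 0.1, 0.3), 2)
  P <- matrix(c(0.2, 0.05, 0.05, 0.4), 2)
  m <- mv_latent_model(c(1, 2), G, P,
                       families = c("gaussian.identity", "gaussian.identity"))
  expect_equal(mv_mean(m), c(1, 2), tolerance = 1e-10)
  expect_equal(mv_phen_cov(m, "expected"), G + P, tolerance = 1e-8)
  expect_equal(g_observed(m), G, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("means are marginal and correlation-free", {
  m <- mv_latent_model(c(0, 0),
                       G = matrix(c(0.5, 0.3, 0.3, 1), 2),
                       P = matrix(0, 2, 2),
                       families = list(qg_family("poisson.log"),
                                       qg_family("binomial.probit")))
  expect_equal(mv_mean(m), c(exp(0.25), 0.5), tolerance = 1e-8)
  m0 <- mv_latent_model(c(0, 0),
                        G = matrix(c(0.5, 0, 0, 1), 2),
                        P = matrix(0, 2, 2),
                        families = list(qg_family("poisson.log"),
                                        qg_family("binomial.probit")))
  expect_equal(mv_mean(m), mv_mean(m0), tolerance = 1e-10)
})

test_that("expected-scale covariance matches the bivariate lognormal form", {
  m <- two_pois(0.2)
  lam <- exp(0.25)
  want <- lam^2 * (exp(matrix(c(0.5, 0.2, 0.2, 0.5), 2)) - 1)
  expect_equal(mv_phen_cov(m, "expected"), want, tolerance = 1e-6)
  # observed scale adds the Poisson noise only on the diagonal
  obs <- mv_phen_cov(m, "observed")
  expect_equal(obs - mv_phen_cov(m, "expected"), diag(lam, 2),
               tolerance = 1e-6)
  # zero latent covariance gives zero data-scale covariance
  expect_lt(abs(mv_phen_cov(two_pois(0), "expected")[1, 2]), 1e-8)
})

test_that("G transforms by the diagonal Psi congruence", {
  m <- two_pois(0.2)
  lam <- exp(0.25)
  got <- g_observed(m)
  expect_equal(attr(got, "psi"), c(lam, lam), tolerance = 1e-8)
  expect_equal(got, lam^2 * matrix(c(0.5, 0.2, 0.2, 0.5), 2),
               tolerance = 1e-6, ignore_attr = TRUE)
  # genetic correlations are untouched by the scaling
  expect_equal(cov2cor(unclass(got)), cov2cor(m$G), tolerance = 1e-8,
               ignore_attr = TRUE)
  ev <- eigen(got, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("one-trait models collapse to the univariate functions", {
  m1 <- mv_latent_model(0.4, G = matrix(0.3), P = matrix(0.2),
                        families = "poisson.log")
  u <- latent_model(0.4, var_a = 0.3, var_re = 0.2, var_o = 0,
                    family = "poisson.log")
  expect_equal(mv_mean(m1), population_mean(u), tolerance = 1e-10)
  expect_equal(mv_phen_cov(m1, "expected")[1, 1], var_expected(u),
               tolerance = 1e-10)
  expect_equal(mv_phen_cov(m1, "observed")[1, 1], var_observed(u),
               tolerance = 1e-10)
  expect_equal(g_observed(m1)[1, 1], va_observed(u), tolerance = 1e-10)
})

test_that("prediction rows are averaged per trait", {
  pred <- cbind(c(-0.5, 0.5), c(0.2, -0.2))
  m <- two_pois(0.2, predicted = pred)
  u1 <- latent_model(0, var_a = 0.5, var_o = 0, family = "poisson.log",
                     predicted = pred[, 1])
  expect_equal(mv_mean(m)[1], population_mean(u1), tolerance = 1e-10)
  expect_equal(attr(g_observed(m), "psi")[1], psi(u1), tolerance = 1e-10)
})

test_that("constructor rejects inconsistent or non-PSD inputs", {
  expect_error(mv_latent_model(c(0, 0), G = matrix(0.5), P = matrix(0, 2, 2),
                               families = c("poisson.log", "poisson.log")),
               "dimensions")
  expect_error(mv_latent_model(c(0, 0),
                               G = matrix(c(1, 2, 2, 1), 2),
                               P = matrix(0, 2, 2),
                               families = c("poisson.log", "poisson.log")),
               "semidefinite")
  expect_error(mv_latent_model(c(0, 0),
                               G = matrix(c(1, 0.2, 0.3, 1), 2),
                               P = matrix(0, 2, 2),
                               families = c("poisson.log", "poisson.log")),
               "symmetric")
})
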