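# Frozen expected values: lognormal/probit closed forms and bivariate-normal
# orthant arithmetic, cross-checked against the trapezoid oracle in the
# helper where quadrature itself is under test.

test_that("population mean matches closed forms per family", {
  expect_equal(population_mean(
    latent_model(3, var_a = 1, var_o = 0.5, family = "gaussian.identity")),
    3, tolerance = 1e-10)
  expect_equal(population_mean(pois_half()), exp(0.25), tolerance = 1e-8)
  expect_equal(population_mean(probit_unit()), 0.5, tolerance = 1e-10)
})

test_that("phenotypic variances split into expected and distribution parts", {
  m <- pois_half()
  lam <- exp(0.25)
  expect_equal(var_expected(m), lam^2 * (exp(0.5) - 1), tolerance = 1e-8)
  expect_equal(var_observed(m), lam^2 * (exp(0.5) - 1) + lam,
               tolerance = 1e-8)
  # binomial(1)/probit at mu=0, V=1: E[Phi(l)^2] is the orthant probability
  # 1/4 + asin(1/2)/(2 pi) = 1/3, so V_P,exp = 1/3 - 1/4 = 1/12
  expect_equal(var_expected(probit_unit()), 1 / 12, tolerance = 1e-8)
  expect_equal(var_observed(probit_unit()), 0.25, tolerance = 1e-8)
  g <- latent_model(0, var_a = 0.4, var_re = 0.3, var_o = 0.3,
                    family = "gaussian.identity")
  expect_equal(var_observed(g), 1, tolerance = 1e-10)
})

test_that("genotypic values and variance follow the nested integrals", {
  m <- latent_model(0, var_a = 0.5, var_re = 0.25, var_o = 0,
                    family = "poisson.log")
  expect_equal(genotypic_value(m, 0), exp(0.125), tolerance = 1e-8)
  expect_equal(genotypic_value(probit_unit(var_re = 0), qnorm(0.9)), 0.9,
               tolerance = 1e-8)
  m2 <- pois_half()
  expect_equal(genotypic_variance(m2), exp(0.5) * (exp(0.5) - 1),
               tolerance = 1e-6)
  expect_identical(genotypic_variance(probit_unit(var_a = 0, var_re = 1)), 0)
  g <- latent_model(1, var_a = 0.3, var_re = 0.2, var_o = 0,
                    family = "gaussian.identity")
  expect_equal(genotypic_variance(g), 0.3, tolerance = 1e-8)
})

test_that("Psi and the data-scale additive variance match closed forms", {
  expect_equal(psi(pois_half()), exp(0.25), tolerance = 1e-8)
  expect_equal(psi(probit_unit()), dnorm(0) / sqrt(2), tolerance = 1e-8)
  expect_equal(va_observed(pois_half()), exp(0.5) * 0.5, tolerance = 1e-7)
  expect_equal(va_observed(probit_unit()), dnorm(0)^2 / 2, tolerance = 1e-8)
  expect_identical(va_observed(probit_unit(var_a = 0, var_re = 1)), 0)
})

test_that("the parameter bundle reduces to the LMM case for identity/gaussian", {
  g <- qg_params(latent_model(2, var_a = 0.4, var_re = 0.1, var_o = 0.5,
                              family = "gaussian.identity"))
  expect_equal(g$h2_lat, 0.4, tolerance = 1e-10)
  expect_equal(g$h2_exp, 0.4, tolerance = 1e-8)
  expect_equal(g$h2_obs, 0.4, tolerance = 1e-8)
  expect_equal(g$H2_obs, 0.4, tolerance = 1e-6)
  expect_equal(g$psi, 1, tolerance = 1e-12)
  expect_equal(g$var_p_obs, 1, tolerance = 1e-8)
  expect_equal(g$mean_obs, 2, tolerance = 1e-10)
})

test_that("numerical bundle obeys the ordering invariants on a grid", {
  for (mu in c(0, 1.5, 3)) {
    for (v in c(0.05, 0.5, 1)) {
      m <- latent_model(mu, var_a = 0.6 * v, var_re = 0.4 * v, var_o = 0,
                        family = "poisson.log")
      q <- qg_params(m, closed_form = "off")
      expect_gte(q$var_p_obs, q$var_p_exp)
      expect_gte(q$var_p_exp, 0)
      expect_lte(q$var_a_obs, q$var_genotypic + 1e-8)
      expect_true(q$h2_obs >= 0 && q$h2_obs <= q$h2_exp &&
                    q$h2_exp <= 1 + 1e-10)
      expect_lte(q$h2_obs, q$H2_obs + 1e-8)
    }
  }
})

test_that("narrow- and broad-sense heritability converge as V_A vanishes", {
  m <- latent_model(0.5, var_a = 0.01, var_re = 0.4, var_o = 0,
                    family = "poisson.log")
  q <- qg_params(m, closed_form = "off")
  expect_lt(abs(q$h2_obs - q$H2_obs) / q$H2_obs, 0.05)
})

test_that("results are invariant to shifting the intercept against predictions", {
  pred <- c(-0.6, -0.1, 0.2, 0.8)
  for (shift in c(-1, 2.5)) {
    a <- qg_params(latent_model(0.3, var_a = 0.2, var_re = 0.1, var_o = 0,
                                family = "poisson.log", predicted = pred),
                   closed_form = "off")
    b <- qg_params(latent_model(0.3 + shift, var_a = 0.2, var_re = 0.1,
                                var_o = 0, family = "poisson.log",
                                predicted = pred - shift),
                   closed_form = "off")
    for (nm in c("mean_obs", "var_p_exp", "var_p_obs", "psi", "var_a_obs",
                 "h2_obs", "var_genotypic")) {
      expect_equal(a[[nm]], b[[nm]], tolerance = 1e-10)
    }
  }
})

test_that("a zero mean makes the standardized measures NA with a warning", {
  m <- latent_model(0, var_a = 0.4, var_re = 0.1, var_o = 0.5,
                    family = "gaussian.identity")
  expect_warning(q <- qg_params(m), "undefined")
  expect_true(is.na(q$cv_a) && is.na(q$i_a))
  expect_false(is.na(q$h2_obs))
})

test_that("model construction validates its inputs", {
  expect_error(latent_model(0, var_a = -1, var_o = 0, family = "poisson.log"),
               "nonnegative")
  expect_error(latent_model(0, var_a = 0, var_o = 0, family = "poisson.log"),
               "positive")
  expect_error(latent_model(0, var_a = 1, var_o = 0, family = "poisson.log",
                            predicted = numeric(0)), "nonempty")
})
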