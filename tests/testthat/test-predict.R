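test_that("expected fitness sums fitness against the conditional pmf", {
  m <- pois_half()
  expect_equal(expected_fitness(m, fitness_spec(fun = identity), 1), exp(1),
               tolerance = 1e-8)
  surv <- fitness_spec(k = 0:1, w = c(0, 1))
  expect_equal(expected_fitness(probit_unit(), surv, 0), 0.5,
               tolerance = 1e-12)
  const <- fitness_spec(fun = function(k) rep(2.7, length(k)))
  expect_equal(expected_fitness(m, const, c(-1, 0, 2)), rep(2.7, 3),
               tolerance = 1e-8)
})

test_that("mean fitness integrates expected fitness over the latent scale", {
  m <- pois_half()
  expect_equal(mean_fitness(m, fitness_spec(fun = identity)), exp(0.25),
               tolerance = 1e-7)
  expect_equal(mean_fitness(m, fitness_spec(fun = function(k)
    rep(3, length(k)))), 3, tolerance = 1e-8)
  expect_equal(mean_fitness(probit_unit(), fitness_spec(k = 0:1, w = 0:1)),
               0.5, tolerance = 1e-8)
})

test_that("fecundity selection on a Poisson trait gives delta_mu = V_A", {
  fec <- fitness_spec(fun = identity)
  for (mu in c(0, 1)) {
    for (va in c(0.1, 0.5)) {
      m <- latent_model(mu, var_a = va, var_re = 0.2, var_o = 0,
                        family = "poisson.log")
      expect_equal(latent_response(m, fec), va, tolerance = 1e-6)
      r <- data_scale_response(m, fec)
      lam <- exp(mu + (va + 0.2) / 2)
      expect_equal(r$delta_zbar, lam * (exp(va) - 1), tolerance = 1e-5)
    }
  }
})

test_that("linear fitness on a Gaussian trait recovers the breeder's equation", {
  for (beta in c(0.2, 0.5)) {
    for (h2 in c(0.3, 0.8)) {
      m <- latent_model(1, var_a = h2, var_re = 1 - h2, var_o = 0,
                        family = "gaussian.identity")
      fit <- fitness_spec(fun = function(z) 1 + beta * z)
      w_bar <- 1 + beta * 1
      expect_equal(latent_response(m, fit), h2 * beta / w_bar,
                   tolerance = 1e-6)
      r <- data_scale_response(m, fit)
      expect_equal(r$delta_zbar, r$delta_mu, tolerance = 1e-8)
      # R = h2 * S with S = cov(z, W)/W_bar = V_P * beta / W_bar
      s <- 1 * beta / w_bar
      expect_equal(r$delta_zbar, h2 * s, tolerance = 1e-6)
    }
  }
})

test_that("no heritable variance or no selection means no response", {
  m0 <- latent_model(0, var_a = 0, var_re = 0.5, var_o = 0,
                     family = "poisson.log")
  expect_equal(data_scale_response(m0, fitness_spec(fun = identity))$delta_zbar,
               0, tolerance = 1e-10)
  const <- fitness_spec(fun = function(k) rep(1, length(k)))
  expect_equal(latent_response(pois_half(), const), 0, tolerance = 1e-8)
})

test_that("the response is invariant to rescaling fitness", {
  m <- pois_half()
  f1 <- truncation_fitness(m, prop_selected = 0.3)
  f2 <- fitness_spec(fun = function(k) 7.3 * f1$fun(k))
  r1 <- data_scale_response(m, f1)
  r2 <- data_scale_response(m, f2)
  expect_equal(r1$delta_mu, r2$delta_mu, tolerance = 1e-10)
  expect_equal(r1$delta_zbar, r2$delta_zbar, tolerance = 1e-10)
  expect_equal(r2$w_bar, 7.3 * r1$w_bar, tolerance = 1e-8)
})

test_that("monotone increasing fitness yields a nonnegative response", {
  for (prop in c(0.2, 0.5, 0.9)) {
    m <- latent_model(1, var_a = 0.05, var_re = 0.05, var_o = 0,
                      family = "poisson.log")
    expect_gte(latent_response(m, truncation_fitness(m, prop)), 0)
  }
})

test_that("analytic fitness derivatives agree with finite differences", {
  m <- latent_model(0.5, var_a = 0.3, var_re = 0.2, var_o = 0,
                    family = "poisson.log")
  fit <- truncation_fitness(m, prop_selected = 0.4)
  w_exp <- function(l) expected_fitness(m, fit, l)
  h <- 1e-5
  grid <- c(-0.5, 0.3, 1.2)
  fd <- (w_exp(grid + h) - w_exp(grid - h)) / (2 * h)
  dw <- qgscales:::w_exp_function(m, fit, deriv = TRUE)(grid)
  expect_equal(dw, fd, tolerance = 1e-5)
})

test_that("degenerate fitness specifications fail loudly", {
  m <- pois_half()
  expect_error(fitness_spec(k = 0:1, w = c(0, -1)), "nonnegative")
  expect_error(fitness_spec(k = c(0, 0), w = c(1, 1)), "distinct")
  # table too short for the Poisson support: mass above k = 1 is orphaned
  expect_error(mean_fitness(m, fitness_spec(k = 0:1, w = c(0, 1))),
               "category k = 2")
  # all fitness far beyond the reachable counts: mean fitness underflows to 0
  far <- fitness_spec(fun = function(k) as.numeric(k > 1000))
  expect_error(latent_response(m, far), "undefined")
  expect_error(expected_fitness(latent_model(0, 1, 0,
                                             family = "gaussian.identity"),
                                fitness_spec(k = 0:1, w = 0:1), 0),
               "function")
})
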