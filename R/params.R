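#' Population mean phenotype on the data scales
#'
#' The expected mean phenotype \eqn{\bar z}, identical on the expected and
#' observed data scales: the expectation of the inverse link over the latent
#' distribution, averaged over fixed-effect predictions when present.
#'
#' @param model A [latent_model()].
#' @param nodes Number of Gauss-Hermite nodes.
#' @return A single numeric value.
#' @examples
#' m <- latent_model(0, var_a = 0.5, var_o = 0, family = "poisson.log")
#' population_mean(m)  # exp(0.25)
#' @export
population_mean <- function(model, nodes = 64) {
  average_over_predictions(model$family$inv_link, model, nodes = nodes)
}

#' Phenotypic variance on the expected data scale
#'
#' Variance of the expected values \eqn{g^{-1}(\ell)} around the grand mean
#' \eqn{\bar z}. With fixed-effect predictions, the squared deviations are
#' averaged across predictions but taken from the single grand mean, so the
#' variance contributed by the fixed effects themselves is included.
#'
#' @inheritParams population_mean
#' @return A single numeric value.
#' @export
var_expected <- function(model, nodes = 64) {
  zbar <- population_mean(model, nodes = nodes)
  inv <- model$family$inv_link
  average_over_predictions(function(l) (inv(l) - zbar)^2, model, nodes = nodes)
}

#' Phenotypic variance on the observed data scale
#'
#' Adds to [var_expected()] the average distribution-function variance
#' \eqn{E[v(\ell, \theta)]} — the irreducible observation noise around the
#' expected values.
#'
#' @inheritParams population_mean
#' @return A single numeric value.
#' @export
var_observed <- function(model, nodes = 64) {
  var_expected(model, nodes = nodes) +
    average_over_predictions(model$family$var_fun, model, nodes = nodes)
}

#' Genotypic value on the data scales
#'
#' The expected phenotype of an individual with latent additive genetic value
#' `a`: the inverse link integrated over the remaining (non-genetic) latent
#' variance \eqn{V_{RE}+V_O}, averaged over fixed-effect predictions when
#' present.
#'
#' @inheritParams population_mean
#' @param a Latent breeding value(s); vectorized.
#' @return Numeric vector of the same length as `a`.
#' @export
genotypic_value <- function(model, a, nodes = 64) {
  vapply(a, function(ai) {
    average_over_predictions(model$family$inv_link, model,
                             variance = model$var_re + model$var_o,
                             shift = ai, nodes = nodes)
  }, numeric(1))
}

#' Total genotypic variance on the data scales
#'
#' Variance of genotypic values as the latent breeding value varies,
#' \eqn{a \sim N(0, V_{A,\ell})}, computed by an outer Gauss-Hermite
#' quadrature over `a`. Because the link is nonlinear, this exceeds the
#' strictly additive part [va_observed()]: latent additive variance generates
#' both additive and non-additive variance on the data scales.
#'
#' @inheritParams population_mean
#' @return A single numeric value.
#' @export
genotypic_variance <- function(model, nodes = 64) {
  if (model$var_a == 0) return(0)
  zbar <- population_mean(model, nodes = nodes)
  gaussian_expectation(function(a) (genotypic_value(model, a, nodes = nodes) - zbar)^2,
                       0, model$var_a, nodes = nodes)
}

#' Psi: average derivative of the inverse link
#'
#' The expectation of \eqn{dg^{-1}/d\ell} over the latent distribution. By
#' Stein's lemma this is the least-squares slope of data-scale phenotype on
#' latent breeding value, so it converts latent additive genetic (co)variance
#' to the data scales: \eqn{V_{A,obs} = \Psi^2 V_{A,\ell}}.
#'
#' @inheritParams population_mean
#' @return A single numeric value.
#' @export
psi <- function(model, nodes = 64) {
  average_over_predictions(model$family$inv_link_deriv, model, nodes = nodes)
}

#' Additive genetic variance on the data scales
#'
#' \eqn{V_{A,obs} = V_{A,exp} = \Psi^2 V_{A,\ell}}: the variance of breeding
#' values expressed on the expected/observed data scales.
#'
#' @inheritParams population_mean
#' @return A single numeric value.
#' @export
va_observed <- function(model, nodes = 64) {
  psi(model, nodes = nodes)^2 * model$var_a
}

#' Quantitative genetic parameters on the data scales
#'
#' The package's main entry point: computes the full bundle of data-scale
#' quantitative genetic parameters implied by a latent-scale GLMM fit —
#' population mean, expected- and observed-scale phenotypic variances, total
#' genotypic variance, Psi, data-scale additive genetic variance, latent /
#' expected / observed narrow-sense heritabilities, broad-sense heritability,
#' the additive coefficient of variation and evolvability.
#'
#' `closed_form` controls dispatch to the exact analytic route: `"auto"`
#' (default) uses [poisson_log_params()] when the family is `poisson.log`,
#' `"on"` insists on an analytic route (erroring for families without a full
#' one), `"off"` forces quadrature (useful for cross-checking the analytic
#' formulas against the generic engine).
#'
#' When the population mean is zero the mean-standardized measures `cv_a` and
#' `i_a` are undefined and returned as `NA` with a warning.
#'
#' @inheritParams population_mean
#' @param closed_form One of `"auto"`, `"on"`, `"off"`.
#' @return An object of class `qg_params`: a list with elements `mean_obs`,
#'   `var_p_exp`, `var_p_obs`, `var_genotypic`, `psi`, `var_a_obs`, `h2_lat`,
#'   `h2_exp`, `h2_obs`, `H2_obs`, `cv_a`, `i_a` and `method`.
#' @examples
#' m <- latent_model(0, var_a = 0.5, var_o = 0, family = "poisson.log")
#' qg_params(m)
#' @export
qg_params <- function(model, closed_form = c("auto", "on", "off"), nodes = 64) {
  stopifnot(inherits(model, "latent_model"))
  closed_form <- match.arg(closed_form)
  if (closed_form != "off" && model$family$family == "poisson.log") {
    return(poisson_log_params(model))
  }
  if (closed_form == "on") {
    stop("no full closed-form parameter set for family ",
         model$family$family, "; use closed_form = 'auto' or 'off'",
         call. = FALSE)
  }
  zbar <- population_mean(model, nodes = nodes)
  vexp <- var_expected(model, nodes = nodes)
  vobs <- vexp + average_over_predictions(model$family$var_fun, model,
                                          nodes = nodes)
  ps <- psi(model, nodes = nodes)
  vaobs <- ps^2 * model$var_a
  vgeno <- genotypic_variance(model, nodes = nodes)
  new_qg_params(zbar, vexp, vobs, vgeno, ps, vaobs, model,
                method = "quadrature")
}

# Assemble a qg_params bundle from its primary quantities.
new_qg_params <- function(zbar, vexp, vobs, vgeno, ps, vaobs, model, method) {
  total <- model$total_var
  h2_lat <- if (total > 0) model$var_a / total else NA_real_
  if (abs(zbar) <= 1e-10 * max(1, sqrt(abs(vobs)))) {
    warning("population mean is zero; cv_a and i_a are undefined",
            call. = FALSE)
    cv_a <- i_a <- NA_real_
  } else {
    cv_a <- 100 * sqrt(vaobs) / zbar
    i_a <- vaobs / zbar^2
  }
  structure(
    list(mean_obs = zbar, var_p_exp = vexp, var_p_obs = vobs,
         var_genotypic = vgeno, psi = ps, var_a_obs = vaobs,
         h2_lat = h2_lat,
         h2_exp = if (vexp > 0) vaobs / vexp else NA_real_,
         h2_obs = if (vobs > 0) vaobs / vobs else NA_real_,
         H2_obs = if (vobs > 0) vgeno / vobs else NA_real_,
         cv_a = cv_a, i_a = i_a, method = method),
    class = "qg_params"
  )
}

#' @export
print.qg_params <- function(x, digits = 4, ...) {
  cat("Quantitative genetic parameters on the data scales (", x$method,
      ")\n", sep = "")
  lab <- c(mean_obs = "Phenotypic mean (z-bar)",
           var_p_exp = "Phenotypic variance, expected scale (V_P,exp)",
           var_p_obs = "Phenotypic variance, observed scale (V_P,obs)",
           var_genotypic = "Total genotypic variance",
           psi = "Psi (mean inverse-link derivative)",
           var_a_obs = "Additive genetic variance (V_A,obs)",
           h2_lat = "Heritability, latent scale (h2_lat)",
           h2_exp = "Heritability, expected scale (h2_exp)",
           h2_obs = "Heritability, observed scale (h2_obs)",
           H2_obs = "Broad-sense heritability (H2_obs)",
           cv_a = "Additive CV (CV_A, %)",
           i_a = "Evolvability (I_A)")
  for (nm in names(lab)) {
    cat(format(lab[[nm]], width = 46), signif(x[[nm]], digits), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.qg_params <- function(x, ...) {
  as.data.frame(x[setdiff(names(x), "method")], ...)
}
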