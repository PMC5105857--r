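#' Exact parameters for the Poisson/log model
#'
#' For a log link and Poisson distribution both the inverse-link derivative
#' and the distribution variance equal the expected value, so every
#' data-scale parameter has a lognormal closed form. With
#' \eqn{V = V_{A,\ell}+V_{RE}+V_O} and \eqn{\lambda = e^{\mu + V/2}}:
#' \deqn{\bar z = \Psi = \lambda, \quad
#'       V_{P,exp} = \lambda^2(e^{V}-1), \quad
#'       V_{P,obs} = V_{P,exp} + \lambda,}
#' \deqn{V_{A,obs} = \lambda^2 V_{A,\ell}, \quad
#'       V(E[z|a]) = \lambda^2(e^{V_{A,\ell}}-1),}
#' from which \eqn{h^2_{obs} = \lambda V_{A,\ell}/(\lambda(e^V-1)+1)} and
#' \eqn{H^2_{obs} = \lambda(e^{V_{A,\ell}}-1)/(\lambda(e^V-1)+1)}. With
#' fixed-effect predictions, \eqn{\lambda} becomes the average of
#' \eqn{e^{\mu+\hat\ell_i+V/2}} and the second moment averages accordingly.
#' These formulas are exact solutions of the generic quadrature route, which
#' the test suite exploits in both directions.
#'
#' @param model A [latent_model()] with family `poisson.log`.
#' @return A `qg_params` object (see [qg_params()]) with
#'   `method = "closed_form"`.
#' @examples
#' m <- latent_model(0, var_a = 0.5, var_o = 0, family = "poisson.log")
#' poisson_log_params(m)$var_p_obs  # 2.3536
#' @export
poisson_log_params <- function(model) {
  stopifnot(inherits(model, "latent_model"))
  if (model$family$family != "poisson.log") {
    stop("poisson_log_params requires family poisson.log, got ",
         model$family$family, call. = FALSE)
  }
  v <- model$total_var
  means <- latent_means(model)
  lam_i <- exp(means + v / 2)
  lam <- mean(lam_i)
  vexp <- mean(lam_i^2) * exp(v) - lam^2
  vobs <- vexp + lam
  vaobs <- lam^2 * model$var_a
  vgeno <- lam^2 * (exp(model$var_a) - 1)
  new_qg_params(lam, vexp, vobs, vgeno, lam, vaobs, model,
                method = "closed_form")
}

#' Exact observed-scale heritability for the binomial/probit threshold model
#'
#' A binomial(1)/probit GLMM is exactly a threshold (liability) model whose
#' liability scale is the latent scale plus the probit link variance
#' \eqn{V_L = 1}. Heritability on the liability scale is
#' \deqn{h^2_{liab} = V_{A,\ell} / (V_{A,\ell}+V_{RE}+V_O+1),}
#' and the Dempster-Lerner transformation maps it to the observed scale:
#' \deqn{h^2_{obs} = \frac{t^2}{p(1-p)} h^2_{liab},}
#' where \eqn{p} is the probability of occurrence and \eqn{t} the standard
#' normal density at the \eqn{p}th quantile. This is an exact analytic
#' solution of the generic Psi route. With fixed-effect predictions, \eqn{p}
#' and the Psi-bearing numerator are averaged over the predictions
#' (the transformation then reads \eqn{\Psi^2 V_{A,\ell} / (\bar p(1-\bar p))},
#' which reduces to the formula above without predictions).
#'
#' @param model A [latent_model()] with family `binomial.probit` and one
#'   trial.
#' @return A list of class `threshold_params` with elements `liability` (a
#'   list with `h2_liab`, `link_variance`, `p_minor`, `t_density`) and
#'   `h2_obs`.
#' @examples
#' m <- latent_model(0, var_a = 1, var_o = 0, family = "binomial.probit")
#' threshold_params(m)$h2_obs  # 1/pi
#' @export
threshold_params <- function(model) {
  stopifnot(inherits(model, "latent_model"))
  if (model$family$family != "binomial.probit" ||
      model$family$theta$trials != 1) {
    stop("threshold_params requires family binomial.probit with 1 trial",
         call. = FALSE)
  }
  v <- model$total_var
  s <- sqrt(1 + v)
  means <- latent_means(model)
  p_bar <- mean(stats::pnorm(means / s))
  psi_cf <- mean(stats::dnorm(means / s)) / s
  h2_liab <- model$var_a / (v + 1)
  p_minor <- min(p_bar, 1 - p_bar)
  t_dens <- stats::dnorm(stats::qnorm(p_bar))
  h2_obs <- if (p_bar <= 0 || p_bar >= 1) 0 else
    psi_cf^2 * model$var_a / (p_bar * (1 - p_bar))
  structure(
    list(liability = list(h2_liab = h2_liab, link_variance = 1,
                          p_minor = p_minor, t_density = t_dens),
         h2_obs = h2_obs),
    class = "threshold_params"
  )
}

#' @export
print.threshold_params <- function(x, digits = 4, ...) {
  cat("Threshold (liability) model parameters\n")
  cat("  h2 on the liability scale:", signif(x$liability$h2_liab, digits), "\n")
  cat("  link variance V_L:        ", x$liability$link_variance, "\n")
  cat("  p (minor phenotype):      ", signif(x$liability$p_minor, digits), "\n")
  cat("  t = dnorm(qnorm(p)):      ", signif(x$liability$t_density, digits), "\n")
  cat("  h2 on the observed scale: ", signif(x$h2_obs, digits), "\n")
  invisible(x)
}
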