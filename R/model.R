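#' Latent-scale model specification
#'
#' Bundles the latent-scale parameters of a fitted GLMM: the intercept
#' \eqn{\mu}, the additive genetic variance \eqn{V_{A,\ell}}, the summed
#' variance of all other random effects \eqn{V_{RE}}, the overdispersion
#' variance \eqn{V_O}, optionally a vector of marginal fixed-effect
#' predictions \eqn{\hat\ell_i = X\hat{b}}, and the link/distribution family.
#' Every data-scale quantity in the package is an expectation over the normal
#' latent distribution implied by these numbers.
#'
#' `var_o` must be supplied explicitly: for binary models it is unobservable
#' and conventionally fixed (often to 1 for probit/logit analyses), and that
#' identifiability convention belongs to the caller, not to a default.
#'
#' @param mu Latent intercept.
#' @param var_a Latent additive genetic variance, \eqn{\ge 0}.
#' @param var_o Latent overdispersion variance, \eqn{\ge 0} (required).
#' @param var_re Summed variance of non-additive random effects, \eqn{\ge 0}.
#' @param family A [qg_family()] object, or a family name passed on to
#'   [qg_family()].
#' @param predicted Optional numeric vector of fixed-effect predicted latent
#'   values; when present, all parameters are averaged over it.
#' @param theta Extra distribution parameters, used when `family` is a name.
#'
#' @return An object of class `latent_model`.
#' @examples
#' m <- latent_model(mu = 0, var_a = 0.5, var_o = 0, family = "poisson.log")
#' population_mean(m)
#' @export
latent_model <- function(mu, var_a, var_o, var_re = 0, family,
                         predicted = NULL, theta = NULL) {
  if (is.character(family)) family <- qg_family(family, theta = theta)
  stopifnot(inherits(family, "qg_family"))
  for (v in list(mu = mu, var_a = var_a, var_re = var_re, var_o = var_o)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("mu, var_a, var_re and var_o must be finite scalars", call. = FALSE)
    }
  }
  if (var_a < 0 || var_re < 0 || var_o < 0) {
    stop("variance components must be nonnegative", call. = FALSE)
  }
  if (!is.null(predicted)) {
    predicted <- as.numeric(predicted)
    if (length(predicted) == 0L || any(!is.finite(predicted))) {
      stop("predicted must be a nonempty vector of finite latent predictions",
           call. = FALSE)
    }
  }
  total <- var_a + var_re + var_o
  if (total == 0 && !(family$family == "gaussian.identity" &&
                      family$theta$sigma2 > 0)) {
    if (family$family != "gaussian.identity") {
      stop("total latent variance must be positive for non-Gaussian families",
           call. = FALSE)
    }
  }
  structure(
    list(mu = mu, var_a = var_a, var_re = var_re, var_o = var_o,
         total_var = total, predicted = predicted, family = family),
    class = "latent_model"
  )
}

#' @export
print.latent_model <- function(x, ...) {
  cat("<latent_model> ", x$family$family, "\n", sep = "")
  cat("  mu = ", x$mu, ", var_a = ", x$var_a, ", var_re = ", x$var_re,
      ", var_o = ", x$var_o, "\n", sep = "")
  if (!is.null(x$predicted)) {
    cat("  averaged over", length(x$predicted), "fixed-effect predictions\n")
  }
  invisible(x)
}

# Latent means to integrate over: mu alone, or mu + each prediction.
latent_means <- function(model) {
  if (is.null(model$predicted)) model$mu else model$mu + model$predicted
}
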