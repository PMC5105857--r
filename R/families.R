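#' Link/distribution family registry
#'
#' A GLMM connects three scales: a latent scale on which all effects are
#' additive and Gaussian, an expected data scale reached through the inverse
#' link \eqn{g^{-1}}, and an observed data scale on which realized phenotypes
#' scatter around their expectations according to a distribution function.
#' [qg_family()] returns the callable contract for one supported
#' link/distribution pair: the inverse link, its derivative (needed for the
#' Psi scaling of additive variance), the conditional variance function
#' \eqn{v(\ell, \theta)}, and the conditional pmf/density of observations.
#'
#' Supported pairs are `"gaussian.identity"`, `"poisson.log"`,
#' `"binomial.logit"`, `"binomial.probit"` and `"negbin.log"`. Other
#' combinations are rejected rather than silently producing expected values
#' outside the distribution's support.
#'
#' Extra distribution parameters go in `theta`:
#' \describe{
#'   \item{gaussian.identity}{`sigma2` (residual variance of the distribution
#'     function, default 0; latent residual variation is usually carried by
#'     `var_o` instead).}
#'   \item{binomial.*}{`trials` (number of trials, default 1). The expected
#'     data scale is `trials * p`.}
#'   \item{negbin.log}{`theta` (dispersion, > 0), giving variance
#'     \eqn{\lambda + \lambda^2/\theta} with \eqn{\lambda = e^\ell}.}
#' }
#'
#' @param family Character name of the pair, `"distribution.link"`.
#' @param theta Optional named list of extra distribution parameters.
#'
#' @return An object of class `qg_family`: a list with elements `family`,
#'   `dist`, `link`, `theta`, `discrete`, and functions `inv_link(l)`,
#'   `inv_link_deriv(l)`, `var_fun(l)`, `pmf(k, l)`, `support(l)` and
#'   `score(k, l)` (derivative of the log pmf with respect to the latent
#'   value, used for analytic fitness derivatives).
#'
#' @examples
#' fam <- qg_family("poisson.log")
#' fam$inv_link(0)        # 1
#' fam$var_fun(log(2))    # 2, Poisson variance equals the mean
#'
#' bin <- qg_family("binomial.probit", theta = list(trials = 1))
#' bin$pmf(1, 0)          # 0.5
#' @export
qg_family <- function(family, theta = NULL) {
  if (!is.character(family) || length(family) != 1L || !family %in% qg_families()) {
    stop("unknown family '", paste(family, collapse = ","),
         "'; supported families are: ", paste(qg_families(), collapse = ", "),
         call. = FALSE)
  }
  theta <- as.list(theta)
  parts <- strsplit(family, ".", fixed = TRUE)[[1L]]
  out <- switch(family,
    "gaussian.identity" = family_gaussian_identity(theta),
    "poisson.log"       = family_poisson_log(theta),
    "binomial.logit"    = family_binomial(theta, link = "logit"),
    "binomial.probit"   = family_binomial(theta, link = "probit"),
    "negbin.log"        = family_negbin_log(theta)
  )
  out$family <- family
  out$dist <- parts[1L]
  out$link <- parts[2L]
  class(out) <- "qg_family"
  out
}

#' Names of the supported link/distribution pairs
#' @return Character vector of family names accepted by [qg_family()].
#' @export
qg_families <- function() {
  c("gaussian.identity", "poisson.log", "binomial.logit", "binomial.probit",
    "negbin.log")
}

#' @export
print.qg_family <- function(x, ...) {
  th <- if (length(x$theta)) {
    paste0(" [", paste(names(x$theta), unlist(x$theta), sep = "=",
                       collapse = ", "), "]")
  } else ""
  cat("<qg_family> ", x$dist, " distribution, ", x$link, " link", th, "\n",
      sep = "")
  invisible(x)
}

check_theta_num <- function(theta, name, default, lower, family,
                            integer = FALSE) {
  val <- theta[[name]]
  if (is.null(val)) return(default)
  if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val < lower ||
      (integer && val != round(val))) {
    stop("invalid theta parameter '", name, "' for family ", family,
         call. = FALSE)
  }
  val
}

family_gaussian_identity <- function(theta) {
  sigma2 <- check_theta_num(theta, "sigma2", 0, 0, "gaussian.identity")
  list(
    theta = list(sigma2 = sigma2),
    discrete = FALSE,
    inv_link = function(l) l,
    inv_link_deriv = function(l) rep(1, length(l)),
    var_fun = function(l) rep(sigma2, length(l)),
    pmf = function(k, l) {
      if (sigma2 == 0) as.numeric(k == l) else stats::dnorm(k, l, sqrt(sigma2))
    },
    support = function(l) NULL,
    score = NULL
  )
}

family_poisson_log <- function(theta) {
  if (length(theta)) stop("poisson.log takes no theta parameters", call. = FALSE)
  list(
    theta = list(),
    discrete = TRUE,
    inv_link = function(l) exp(l),
    inv_link_deriv = function(l) exp(l),
    var_fun = function(l) exp(l),
    pmf = function(k, l) stats::dpois(k, exp(l)),
    support = function(l) 0:count_upper(exp(l), sqrt(exp(l))),
    # d log P(k|l) / dl for the log link: (k - lambda)
    score = function(k, l) k - exp(l)
  )
}

family_binomial <- function(theta, link) {
  n <- check_theta_num(theta, "trials", 1, 1, paste0("binomial.", link),
                       integer = TRUE)
  p_of <- if (link == "probit") stats::pnorm else stats::plogis
  dp_of <- if (link == "probit") {
    stats::dnorm
  } else {
    function(l) stats::plogis(l) * (1 - stats::plogis(l))
  }
  list(
    theta = list(trials = n),
    discrete = TRUE,
    inv_link = function(l) n * p_of(l),
    inv_link_deriv = function(l) n * dp_of(l),
    var_fun = function(l) { p <- p_of(l); n * p * (1 - p) },
    pmf = function(k, l) stats::dbinom(k, n, p_of(l)),
    support = function(l) 0:n,
    # d log dbinom(k, n, p(l)) / dl = (k - n p) / (p (1 - p)) * dp/dl
    score = function(k, l) {
      p <- p_of(l)
      (k - n * p) / pmax(p * (1 - p), .Machine$double.xmin) * dp_of(l)
    }
  )
}

family_negbin_log <- function(theta) {
  size <- theta[["theta"]]
  if (is.null(size) || !is.numeric(size) || length(size) != 1L ||
      !is.finite(size) || size <= 0) {
    stop("negbin.log requires theta = list(theta = <dispersion > 0>)",
         call. = FALSE)
  }
  list(
    theta = list(theta = size),
    discrete = TRUE,
    inv_link = function(l) exp(l),
    inv_link_deriv = function(l) exp(l),
    var_fun = function(l) { lam <- exp(l); lam + lam^2 / size },
    pmf = function(k, l) stats::dnbinom(k, size = size, mu = exp(l)),
    support = function(l) {
      lam <- exp(l)
      # geometric tail decays slower than Poisson: moment bound + quantile
      hi <- max(count_upper(lam, sqrt(lam + lam^2 / size)),
                stats::qnbinom(1e-14, size = size, mu = max(lam),
                               lower.tail = FALSE) + 30L)
      0:hi
    },
    # d log f / dl = (k/mu - (k + size)/(mu + size)) * mu
    score = function(k, l) {
      mu <- exp(l)
      k - (k + size) * mu / (mu + size)
    }
  )
}

# Adaptive truncation of a count support: mean + 12 sd, floor of 50.
count_upper <- function(mean, sd) {
  max(50L, as.integer(ceiling(max(mean + 12 * sd))))
}

#' Moments of the observation distribution at a fixed latent value
#'
#' Computes the mean (`order = 1`) or variance (`order = 2`) of
#' \eqn{P(Z = k \mid \ell)} by direct summation over the truncated support
#' (analytically for the Gaussian family, whose support is continuous). Mostly
#' useful for checking that a family's `pmf`, `inv_link` and `var_fun` are
#' mutually coherent: the first moment must equal the inverse link and the
#' second central moment the variance function.
#'
#' @param family A [qg_family()] object.
#' @param latent Latent value \eqn{\ell} (scalar).
#' @param order 1 for the mean, 2 for the central second moment (variance).
#'
#' @return A single numeric value.
#' @examples
#' pmf_moments(qg_family("poisson.log"), latent = 1, order = 2)  # exp(1)
#' @export
pmf_moments <- function(family, latent, order = 1) {
  stopifnot(inherits(family, "qg_family"), length(latent) == 1L,
            is.finite(latent))
  if (!order %in% c(1, 2)) stop("order must be 1 or 2", call. = FALSE)
  if (!family$discrete) {
    # gaussian.identity: moments are available in closed form
    return(if (order == 1) family$inv_link(latent) else family$theta$sigma2)
  }
  k <- family$support(latent)
  p <- family$pmf(k, latent)
  mass <- sum(p)
  if (mass < 1 - 1e-12) {
    stop("support truncation at k = ", max(k), " captures only mass ", mass,
         " for latent value ", latent, call. = FALSE)
  }
  m1 <- sum(k * p) / mass
  if (order == 1) m1 else sum((k - m1)^2 * p) / mass
}
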