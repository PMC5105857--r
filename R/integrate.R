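#' Expectation of a function over a normal latent distribution
#'
#' Computes \eqn{E[f(\ell)]} for \eqn{\ell \sim N(m, V)} by Gauss-Hermite
#' quadrature. This is the kernel of every data-scale computation in the
#' package: population means, phenotypic variances, Psi and mean fitness are
#' all expectations of link-derived functions over the latent distribution.
#'
#' With `variance = 0` the latent distribution is a point mass and `f(mean)`
#' is returned directly. `f` must be vectorized and finite at all quadrature
#' nodes (roughly `mean` plus/minus 10 latent standard deviations).
#'
#' @param f Vectorized function of a latent value.
#' @param mean Latent mean \eqn{m}.
#' @param variance Latent variance \eqn{V \ge 0}.
#' @param nodes Number of Gauss-Hermite nodes (default 64).
#'
#' @return A single numeric value.
#' @examples
#' gaussian_expectation(exp, mean = 0, variance = 0.5)  # exp(0.25)
#' @export
gaussian_expectation <- function(f, mean, variance, nodes = 64) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(variance), length(variance) == 1L, variance >= 0)
  if (variance == 0) return(f(mean))
  gh <- gh_rule(nodes)
  l <- mean + sqrt(2 * variance) * gh$x
  vals <- f(l)
  if (any(!is.finite(vals))) {
    stop("integrand is not finite at latent value ",
         signif(l[which(!is.finite(vals))[1L]], 6), call. = FALSE)
  }
  sum(gh$w * vals) / sqrt(pi)
}

# Cached Gauss-Hermite rule (physicists' convention, weight exp(-x^2)).
gh_env <- new.env(parent = emptyenv())
gh_rule <- function(nodes) {
  stopifnot(is.numeric(nodes), length(nodes) == 1L, nodes >= 2)
  key <- as.character(as.integer(nodes))
  if (is.null(gh_env[[key]])) gh_env[[key]] <- pracma::gaussHermite(as.integer(nodes))
  gh_env[[key]]
}

#' Expectation averaged over fixed-effect predictions
#'
#' Marginalizes over fixed effects by averaging the latent expectation across
#' the model's predicted values: returns
#' \eqn{\frac{1}{N}\sum_i E[f(\ell)]} with
#' \eqn{\ell \sim N(\mu + \hat\ell_i, V_{A,\ell}+V_{RE}+V_O)}. Without
#' predictions this is a single expectation at the intercept.
#'
#' @param f Vectorized function of a latent value.
#' @param model A [latent_model()].
#' @param variance Latent variance to integrate over; defaults to the model's
#'   total latent variance (genotypic-value computations pass
#'   \eqn{V_{RE}+V_O} and add the genetic value to the means instead).
#' @param shift Scalar added to every latent mean (used for genotypic values
#'   and selection-response shifts).
#' @param nodes Number of Gauss-Hermite nodes.
#'
#' @return A single numeric value.
#' @export
average_over_predictions <- function(f, model, variance = model$total_var,
                                     shift = 0, nodes = 64) {
  stopifnot(inherits(model, "latent_model"))
  means <- latent_means(model) + shift
  if (length(means) == 1L) {
    return(gaussian_expectation(f, means, variance, nodes = nodes))
  }
  if (variance == 0) return(mean(f(means)))
  gh <- gh_rule(nodes)
  # nodes x predictions matrix of latent values, one quadrature per column
  l <- outer(sqrt(2 * variance) * gh$x, means, `+`)
  vals <- f(l)
  if (any(!is.finite(vals))) {
    stop("integrand is not finite at latent value ",
         signif(l[which(!is.finite(vals))[1L]], 6), call. = FALSE)
  }
  dim(vals) <- dim(l)
  mean(colSums(gh$w * vals)) / sqrt(pi)
}

#' Covariate distribution for integrating over fixed effects
#'
#' Describes the population distribution of fixed covariates when the sampled
#' design matrix is not representative. Three forms are accepted:
#' an explicit set of representative predicted latent values (`values`), a
#' sampler over covariate vectors together with the fixed-effect coefficients
#' (`sampler` and `coef`), or a univariate density with finite support
#' (`density`, `support`, `coef`), which is checked for normalization.
#'
#' @param values Representative predicted latent values \eqn{X\hat b}.
#' @param sampler Function `n -> n x p matrix` (or length-n vector) of
#'   covariate draws.
#' @param coef Fixed-effect coefficient vector \eqn{\hat b} matching the
#'   sampler's columns (or the scalar covariate of `density`).
#' @param density Univariate density function of the covariate.
#' @param support Length-2 numeric range on which `density` lives.
#'
#' @return An object of class `covariate_distribution`.
#' @export
covariate_distribution <- function(values = NULL, sampler = NULL, coef = NULL,
                                   density = NULL, support = NULL) {
  given <- c(values = !is.null(values), sampler = !is.null(sampler),
             density = !is.null(density))
  if (sum(given) != 1L) {
    stop("supply exactly one of values, sampler or density", call. = FALSE)
  }
  if (!is.null(values)) {
    values <- as.numeric(values)
    if (!length(values) || any(!is.finite(values))) {
      stop("values must be finite and nonempty", call. = FALSE)
    }
    out <- list(type = "values", values = values)
  } else if (!is.null(sampler)) {
    if (is.null(coef)) stop("sampler requires coef", call. = FALSE)
    out <- list(type = "sampler", sampler = sampler, coef = as.numeric(coef))
  } else {
    if (is.null(support) || length(support) != 2L || !all(is.finite(support))) {
      stop("density requires a finite support range", call. = FALSE)
    }
    mass <- stats::integrate(density, support[1L], support[2L])$value
    if (abs(mass - 1) > 1e-6) {
      stop("density integrates to ", signif(mass, 6), " over its support; ",
           "it must be normalized", call. = FALSE)
    }
    if (is.null(coef)) coef <- 1
    out <- list(type = "density", density = density, support = support,
                coef = as.numeric(coef))
  }
  structure(out, class = "covariate_distribution")
}

#' Expectation integrated over a covariate distribution
#'
#' Evaluates the double integral of `f` over the latent value and a
#' distribution of fixed covariates,
#' \eqn{\int\!\!\int f(\ell)\, f_N(\ell; \mu + X\hat b, V)\, f_X(X)\, dX d\ell}.
#' A representative-values distribution reduces exactly to
#' [average_over_predictions()]; a univariate density is handled by Gauss
#' quadrature over the covariate; a general sampler by Monte Carlo.
#'
#' @param f Vectorized function of a latent value.
#' @param model A [latent_model()]; its `predicted` slot is ignored here in
#'   favor of `covariates`.
#' @param covariates A [covariate_distribution()].
#' @param nodes Gauss-Hermite nodes for the latent integral.
#' @param n_mc Monte-Carlo sample size for the sampler form.
#' @param seed Optional seed for the Monte-Carlo draw.
#'
#' @return A single numeric value.
#' @export
integrate_over_covariates <- function(f, model, covariates, nodes = 64,
                                      n_mc = 1e5, seed = NULL) {
  stopifnot(inherits(model, "latent_model"),
            inherits(covariates, "covariate_distribution"))
  expect_at <- function(preds) {
    m <- model
    m$predicted <- preds
    average_over_predictions(f, m, nodes = nodes)
  }
  switch(covariates$type,
    values = expect_at(covariates$values),
    sampler = {
      if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
      }
      x <- covariates$sampler(n_mc)
      x <- if (is.null(dim(x))) matrix(x, ncol = 1L) else as.matrix(x)
      expect_at(drop(x %*% covariates$coef))
    },
    density = {
      # Gauss-Legendre over the covariate, Gauss-Hermite over the latent value
      gl <- pracma::gaussLegendre(128, covariates$support[1L],
                                  covariates$support[2L])
      w <- gl$w * covariates$density(gl$x)
      vals <- vapply(gl$x * covariates$coef, function(p) {
        gaussian_expectation(f, model$mu + p, model$total_var, nodes = nodes)
      }, numeric(1))
      sum(w * vals)
    }
  )
}
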