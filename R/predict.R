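#' Fitness on the observed data scale
#'
#' Specifies the fitness \eqn{W_P(k)} of each observed-scale category
#' \eqn{k}, either as a table (`k`, `w`) for discrete traits or as a
#' function of the observed value (required for Gaussian traits, allowed for
#' discrete ones). Fitness values must be finite and nonnegative, with at
#' least one positive value. Only relative fitness matters for the predicted
#' response: rescaling `w` by a positive constant changes nothing downstream.
#'
#' @param k Integer vector of observed categories (table form).
#' @param w Numeric vector of fitness values matching `k`.
#' @param fun Function mapping observed values to fitness (function form).
#' @return An object of class `fitness_spec`.
#' @examples
#' fecundity <- fitness_spec(fun = identity)     # fitness = the count itself
#' survival <- fitness_spec(k = 0:1, w = c(0, 1))
#' @export
fitness_spec <- function(k = NULL, w = NULL, fun = NULL) {
  if (is.null(fun)) {
    if (is.null(k) || is.null(w) || length(k) != length(w) || !length(k)) {
      stop("table form requires k and w of equal positive length",
           call. = FALSE)
    }
    k <- as.integer(k)
    if (anyDuplicated(k) || any(k < 0)) {
      stop("k must be distinct nonnegative categories", call. = FALSE)
    }
    check_fitness_values(w)
    spec <- list(type = "table", k = k, w = as.numeric(w))
  } else {
    stopifnot(is.function(fun))
    spec <- list(type = "function", fun = fun)
  }
  structure(spec, class = "fitness_spec")
}

check_fitness_values <- function(w) {
  if (any(!is.finite(w)) || any(w < 0) || !any(w > 0)) {
    stop("fitness values must be finite, nonnegative, with at least one ",
         "positive", call. = FALSE)
  }
  invisible(w)
}

# W_P over the categories 0..kmax, NA where the table is silent.
fitness_on_support <- function(fitness, kmax) {
  k <- 0:kmax
  if (fitness$type == "function") {
    w <- fitness$fun(k)
    check_fitness_values(w)
    w
  } else {
    w <- rep(NA_real_, kmax + 1L)
    keep <- fitness$k <= kmax
    w[fitness$k[keep] + 1L] <- fitness$w[keep]
    w
  }
}

#' Expected fitness given a latent value
#'
#' \eqn{W_{exp}(\ell) = \sum_k W_P(k) P(Z = k \mid \ell)}: the fitness an
#' individual with latent value \eqn{\ell} expects once the distribution
#' noise around its expected value is accounted for. For Gaussian traits with
#' zero residual distribution variance this is just \eqn{W(\ell)} (function
#' form required).
#'
#' @param model A [latent_model()].
#' @param fitness A [fitness_spec()].
#' @param latent Latent value(s); vectorized.
#' @return Numeric vector of expected fitness values.
#' @export
expected_fitness <- function(model, fitness, latent) {
  stopifnot(inherits(model, "latent_model"), inherits(fitness, "fitness_spec"))
  w_exp <- w_exp_function(model, fitness)
  orphan <- attr(w_exp, "orphan_mass")
  if (!is.null(orphan)) {
    mass <- orphan(latent)
    if (any(mass > 1e-8)) {
      stop("fitness undefined for category k = ",
           attr(w_exp, "first_orphan"),
           " which carries nonnegligible probability mass", call. = FALSE)
    }
  }
  w_exp(latent)
}

# Errors when the fitness table leaves categories uncovered that carry
# nonnegligible probability under the latent distribution.
check_orphan_mass <- function(model, w_exp, nodes) {
  orphan <- attr(w_exp, "orphan_mass")
  if (is.null(orphan)) return(invisible())
  mass <- average_over_predictions(orphan, model, nodes = nodes)
  if (mass > 1e-8) {
    stop("fitness undefined for category k = ", attr(w_exp, "first_orphan"),
         " which carries probability mass ", signif(mass, 3), call. = FALSE)
  }
  invisible()
}

# Builds the vectorized W_exp(l) (and, on request, its analytic derivative).
w_exp_function <- function(model, fitness, deriv = FALSE) {
  fam <- model$family
  if (!fam$discrete) {
    if (fitness$type != "function") {
      stop("Gaussian traits need a fitness function, not a category table",
           call. = FALSE)
    }
    s2 <- fam$theta$sigma2
    w_exp <- if (s2 == 0) fitness$fun else function(l) {
      vapply(l, function(li)
        gaussian_expectation(fitness$fun, li, s2), numeric(1))
    }
    if (!deriv) return(w_exp)
    h <- 1e-4 * sqrt(max(model$total_var, 1))
    return(function(l) (w_exp(l + h) - w_exp(l - h)) / (2 * h))
  }
  out <- function(l) {
    l <- as.numeric(l)
    kmax <- max(vapply(range(l), function(li) max(fam$support(li)),
                       numeric(1)))
    k <- 0:kmax
    w <- fitness_on_support(fitness, kmax)
    w[is.na(w)] <- 0  # uncovered categories: caller checks orphan mass
    p <- outer(k, l, fam$pmf)
    if (deriv) p <- p * outer(k, l, fam$score)
    as.numeric(crossprod(w, p))
  }
  if (fitness$type == "table") {
    # mass of categories the table does not cover, as a function of l
    attr(out, "orphan_mass") <- function(l) {
      l <- as.numeric(l)
      kmax <- max(vapply(range(l), function(li) max(fam$support(li)),
                         numeric(1)))
      k <- 0:kmax
      covered <- !is.na(fitness_on_support(fitness, kmax))
      as.numeric(crossprod(as.numeric(!covered), outer(k, l, fam$pmf)))
    }
    attr(out, "first_orphan") <- min(setdiff(
      0:(max(fitness$k) + 1L), fitness$k))
  }
  out
}

#' Population mean fitness
#'
#' \eqn{\bar W}: the expectation of [expected_fitness()] over the latent
#' distribution, averaged over fixed-effect predictions when present.
#'
#' @inheritParams expected_fitness
#' @param nodes Gauss-Hermite nodes.
#' @return A single numeric value.
#' @export
mean_fitness <- function(model, fitness, nodes = 64) {
  stopifnot(inherits(model, "latent_model"), inherits(fitness, "fitness_spec"))
  w_exp <- w_exp_function(model, fitness)
  check_orphan_mass(model, w_exp, nodes)
  average_over_predictions(w_exp, model, nodes = nodes)
}

#' Predicted response to selection on the latent scale
#'
#' The latent scale satisfies the assumptions of the breeder's/Lande
#' machinery (breeding values and phenotypes jointly Gaussian), so the
#' response of the latent mean is
#' \deqn{\Delta\mu = V_{A,\ell}\, E\!\left[\frac{dW_{exp}}{d\ell}\right]
#'       \frac{1}{\bar W},}
#' Stein's lemma having turned the breeding-value/fitness covariance into an
#' average fitness gradient. The derivative of \eqn{W_{exp}} is computed
#' analytically through the family's score function for discrete families,
#' and by central finite differences for Gaussian ones.
#'
#' @inheritParams mean_fitness
#' @return \eqn{\Delta\mu}, a single numeric value.
#' @export
latent_response <- function(model, fitness, nodes = 64) {
  stopifnot(inherits(model, "latent_model"), inherits(fitness, "fitness_spec"))
  w_bar <- mean_fitness(model, fitness, nodes = nodes)
  check_mean_fitness(model, fitness, w_bar, nodes)
  dw <- average_over_predictions(
    w_exp_function(model, fitness, deriv = TRUE), model, nodes = nodes)
  model$var_a * dw / w_bar
}

# W-bar must be positive and carried by the bulk of the latent distribution,
# not by quadrature-tail artifacts (fitness concentrated on unreachable
# categories underflows W-bar to a meaningless sliver).
check_mean_fitness <- function(model, fitness, w_bar, nodes) {
  w_exp <- w_exp_function(model, fitness)
  gh <- gh_rule(nodes)
  l <- model$mu + sqrt(2 * max(model$total_var, 1e-12)) * gh$x
  w_max <- max(w_exp(l))
  if (!(w_bar > 0) || w_bar < 1e-12 * w_max) {
    stop("mean fitness is (numerically) zero: selection response is ",
         "undefined", call. = FALSE)
  }
  invisible()
}

#' Predicted response to selection on the data scale
#'
#' Chains the latent-scale prediction into a data-scale one: the latent mean
#' is shifted by \eqn{\Delta\mu} (each fixed-effect prediction shifting with
#' it, the offspring generation being assumed to see the same covariate
#' distribution as the parental one) and the population mean recomputed;
#' the response is the difference from the current mean. This is the
#' *permanent* response: the transient reduction of latent variance caused by
#' selection-induced linkage disequilibrium (Bulmer effect) is not modeled,
#' so the observed single-generation (immediate) response will typically fall
#' slightly short of it.
#'
#' @inheritParams mean_fitness
#' @return An object of class `selection_response`: a list with `w_bar`,
#'   `delta_mu` and `delta_zbar`.
#' @examples
#' m <- latent_model(0, var_a = 0.5, var_o = 0, family = "poisson.log")
#' data_scale_response(m, fitness_spec(fun = identity))
#' @export
data_scale_response <- function(model, fitness, nodes = 64) {
  stopifnot(inherits(model, "latent_model"), inherits(fitness, "fitness_spec"))
  w_bar <- mean_fitness(model, fitness, nodes = nodes)
  check_mean_fitness(model, fitness, w_bar, nodes)
  dw <- average_over_predictions(
    w_exp_function(model, fitness, deriv = TRUE), model, nodes = nodes)
  delta_mu <- model$var_a * dw / w_bar
  zbar <- population_mean(model, nodes = nodes)
  zbar_after <- average_over_predictions(model$family$inv_link, model,
                                         shift = delta_mu, nodes = nodes)
  structure(list(w_bar = w_bar, delta_mu = delta_mu,
                 delta_zbar = zbar_after - zbar),
            class = "selection_response")
}

#' @export
print.selection_response <- function(x, digits = 4, ...) {
  cat("Predicted response to selection (via the latent scale)\n")
  cat("  mean fitness W-bar:       ", signif(x$w_bar, digits), "\n")
  cat("  latent response d-mu:     ", signif(x$delta_mu, digits), "\n")
  cat("  data-scale response d-z:  ", signif(x$delta_zbar, digits), "\n")
  invisible(x)
}
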