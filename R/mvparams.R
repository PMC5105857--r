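#' Multivariate latent-scale model
#'
#' Latent parameterization of a multiresponse GLMM: a vector of latent
#' intercepts, the latent additive genetic covariance matrix
#' \eqn{G_\ell}, the summed covariance of all other random effects plus
#' overdispersion, and one link/distribution family per trait. The
#' vector-valued inverse link acts elementwise, so its Jacobian — and hence
#' the multivariate Psi — is diagonal.
#'
#' @param mu Numeric vector of latent intercepts (length d).
#' @param G d x d latent additive genetic covariance matrix.
#' @param P d x d covariance matrix of the remaining latent random effects
#'   (including overdispersion).
#' @param families Length-d list of [qg_family()] objects, or a character
#'   vector of family names.
#' @param predicted Optional N x d matrix of fixed-effect predicted latent
#'   values (one column per trait).
#'
#' @return An object of class `mv_latent_model`.
#' @export
mv_latent_model <- function(mu, G, P, families, predicted = NULL) {
  mu <- as.numeric(mu)
  d <- length(mu)
  G <- as.matrix(G); P <- as.matrix(P)
  if (is.character(families)) families <- lapply(families, qg_family)
  if (!all(dim(G) == d) || !all(dim(P) == d) || length(families) != d) {
    stop("dimensions of mu, G, P and families must agree", call. = FALSE)
  }
  for (m in list(G = G, P = P)) {
    if (max(abs(m - t(m))) > 1e-8) {
      stop("G and P must be symmetric", call. = FALSE)
    }
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("G and P must be positive semidefinite", call. = FALSE)
    }
  }
  stopifnot(all(vapply(families, inherits, logical(1), "qg_family")))
  if (!is.null(predicted)) {
    predicted <- as.matrix(predicted)
    if (ncol(predicted) != d || nrow(predicted) == 0L ||
        any(!is.finite(predicted))) {
      stop("predicted must be a nonempty N x d matrix of finite values",
           call. = FALSE)
    }
  }
  structure(list(mu = mu, G = G, P = P, families = families,
                 predicted = predicted, d = d),
            class = "mv_latent_model")
}

# Univariate marginal model for one trait of a multivariate model. The
# trait's latent variance is split as var_a = G[i,i], var_re = P[i,i]; the
# univariate functions only ever use var_a and the total, so lumping the
# remainder into var_re is exact.
mv_marginal <- function(model, i) {
  latent_model(mu = model$mu[i], var_a = model$G[i, i], var_o = 0,
               var_re = model$P[i, i], family = model$families[[i]],
               predicted = if (is.null(model$predicted)) NULL else
                 model$predicted[, i])
}

#' Mean phenotypes of a multivariate model
#'
#' Elementwise expectation of each trait's inverse link under its marginal
#' latent normal; because the vector-valued link acts elementwise, means
#' depend only on the marginals, not on latent correlations.
#'
#' @param model An [mv_latent_model()].
#' @param nodes Gauss-Hermite nodes per dimension.
#' @return Numeric vector of length d.
#' @export
mv_mean <- function(model, nodes = 64) {
  stopifnot(inherits(model, "mv_latent_model"))
  vapply(seq_len(model$d), function(i) {
    population_mean(mv_marginal(model, i), nodes = nodes)
  }, numeric(1))
}

#' Phenotypic covariance matrix on the expected or observed scale
#'
#' Covariance of the vector of expected values \eqn{g^{-1}(\ell)} under the
#' full latent normal. Each entry depends only on the bivariate latent
#' marginal of the two traits involved, so entries are computed by
#' two-dimensional tensor-product Gauss-Hermite quadrature (exact in any
#' total dimension d). On the observed scale, the distribution noise is
#' conditionally independent across traits given the latent values, so only
#' the diagonal gains the average variance-function terms
#' \eqn{E[v_i(\ell_i)]}.
#'
#' If numerical error drives the result off the positive semidefinite cone,
#' the matrix is projected back (eigenvalue clipping) with a warning and the
#' attribute `projected = TRUE`.
#'
#' @inheritParams mv_mean
#' @param scale `"expected"` or `"observed"`.
#' @return d x d covariance matrix.
#' @export
mv_phen_cov <- function(model, scale = c("expected", "observed"), nodes = 64) {
  stopifnot(inherits(model, "mv_latent_model"))
  scale <- match.arg(scale)
  d <- model$d
  sigma <- model$G + model$P
  zbar <- mv_mean(model, nodes = nodes)
  out <- matrix(0, d, d)
  for (i in seq_len(d)) {
    mi <- mv_marginal(model, i)
    out[i, i] <- var_expected(mi, nodes = nodes)
    if (scale == "observed") {
      out[i, i] <- out[i, i] +
        average_over_predictions(mi$family$var_fun, mi, nodes = nodes)
    }
  }
  if (d > 1) {
    for (i in seq_len(d - 1)) {
      for (j in (i + 1):d) {
        eij <- bivariate_link_moment(model, i, j, sigma, nodes = nodes)
        out[i, j] <- out[j, i] <- eij - zbar[i] * zbar[j]
      }
    }
  }
  ev <- eigen(out, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1)) {
    warning("phenotypic covariance left the PSD cone numerically; ",
            "projected back by eigenvalue clipping", call. = FALSE)
    out <- ev$vectors %*% diag(pmax(ev$values, 0), d) %*% t(ev$vectors)
    attr(out, "projected") <- TRUE
  }
  out
}

# E[g_i^{-1}(l_i) g_j^{-1}(l_j)] under the bivariate latent marginal of
# traits i and j, averaged over prediction rows when present.
bivariate_link_moment <- function(model, i, j, sigma, nodes = 64) {
  s2 <- sigma[c(i, j), c(i, j)]
  fi <- model$families[[i]]$inv_link
  fj <- model$families[[j]]$inv_link
  # factor s2 = L L^T through the eigendecomposition (works for any PSD s2)
  ev <- eigen(s2, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2)
  gh <- gh_rule(nodes)
  grid <- as.matrix(expand.grid(x1 = gh$x, x2 = gh$x))
  w <- as.vector(outer(gh$w, gh$w)) / pi
  dev <- sqrt(2) * grid %*% t(L)  # quadrature deviations on the latent scale
  means <- if (is.null(model$predicted)) {
    matrix(model$mu[c(i, j)], nrow = 1)
  } else {
    cbind(model$mu[i] + model$predicted[, i],
          model$mu[j] + model$predicted[, j])
  }
  vals <- vapply(seq_len(nrow(means)), function(r) {
    sum(w * fi(means[r, 1] + dev[, 1]) * fj(means[r, 2] + dev[, 2]))
  }, numeric(1))
  mean(vals)
}

#' Additive genetic covariance matrix on the observed scale
#'
#' The multivariate analogue of \eqn{V_{A,obs} = \Psi^2 V_{A,\ell}}:
#' \deqn{G_{obs} = \Psi G_\ell \Psi^T,}
#' where \eqn{\Psi} is the diagonal matrix of per-trait average inverse-link
#' derivatives, each computed on the trait's latent marginal (averaged over
#' prediction rows when present). The congruence transform preserves
#' symmetry and positive semidefiniteness, and leaves genetic correlations
#' unchanged.
#'
#' @inheritParams mv_mean
#' @return d x d matrix with attribute `psi` (the per-trait Psi values).
#' @export
g_observed <- function(model, nodes = 64) {
  stopifnot(inherits(model, "mv_latent_model"))
  psis <- vapply(seq_len(model$d), function(i) {
    psi(mv_marginal(model, i), nodes = nodes)
  }, numeric(1))
  out <- diag(psis, model$d) %*% model$G %*% diag(psis, model$d)
  attr(out, "psi") <- psis
  out
}
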