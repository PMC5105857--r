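#' Apply a parameter computation across posterior samples
#'
#' Uncertainty in GLMM variance components is naturally propagated by
#' recomputing the derived data-scale parameters for every posterior sample
#' of the latent parameters. `map_posterior` builds a [latent_model()] from
#' each row of a sample table (columns `mu`, `var_a`, `var_o`, optionally
#' `var_re`) and applies `fun` to it, collecting the numeric outputs
#' row-wise. Rows with invalid parameters (non-finite values or negative
#' variances) or rows on which `fun` fails are flagged and returned as `NA`
#' rather than aborting the run; their count is reported in a warning and in
#' the `n_failed` attribute.
#'
#' @param samples Data frame (or matrix) of posterior samples, one row per
#'   sample, with named columns `mu`, `var_a`, `var_o` and optionally
#'   `var_re`.
#' @param fun Function of a `latent_model` returning a named list or vector
#'   of numbers (default [qg_params()]).
#' @param family A [qg_family()] object or family name shared by all rows.
#' @param theta Extra distribution parameters when `family` is a name.
#' @param predicted Fixed-effect predictions: a single numeric vector shared
#'   by all samples, or a list of length `nrow(samples)` with one vector per
#'   sample.
#' @param ... Further arguments passed to `fun`.
#' @return Data frame of per-sample outputs with attribute `n_failed`.
#' @examples
#' post <- data.frame(mu = c(0, 0), var_a = c(0.5, 0.25), var_o = 0)
#' map_posterior(post, family = "poisson.log")$h2_obs
#' @export
map_posterior <- function(samples, fun = qg_params, family, theta = NULL,
                          predicted = NULL, ...) {
  samples <- as.data.frame(samples)
  needed <- c("mu", "var_a", "var_o")
  if (!all(needed %in% names(samples))) {
    stop("posterior table must contain columns mu, var_a, var_o ",
         "(and optionally var_re); missing: ",
         paste(setdiff(needed, names(samples)), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(samples) < 2L) stop("need at least 2 posterior samples",
                               call. = FALSE)
  if (!"var_re" %in% names(samples)) samples$var_re <- 0
  if (is.character(family)) family <- qg_family(family, theta = theta)
  per_sample_pred <- is.list(predicted) && !is.data.frame(predicted)
  if (per_sample_pred && length(predicted) != nrow(samples)) {
    stop("per-sample predicted list must have one element per row",
         call. = FALSE)
  }
  rows <- vector("list", nrow(samples))
  failed <- logical(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    rows[[i]] <- tryCatch({
      model <- latent_model(mu = samples$mu[i], var_a = samples$var_a[i],
                            var_re = samples$var_re[i],
                            var_o = samples$var_o[i], family = family,
                            predicted = if (per_sample_pred) predicted[[i]]
                                        else predicted)
      res <- fun(model, ...)
      vapply(Filter(is.numeric, unclass(res)), as.numeric, numeric(1))
    }, error = function(e) NULL)
    failed[i] <- is.null(rows[[i]])
  }
  if (all(failed)) stop("computation failed on every posterior sample",
                        call. = FALSE)
  template <- rows[[which(!failed)[1L]]]
  for (i in which(failed)) {
    rows[[i]] <- stats::setNames(rep(NA_real_, length(template)),
                                 names(template))
  }
  if (any(failed)) {
    warning(sum(failed), " of ", nrow(samples),
            " posterior samples failed and were returned as NA",
            call. = FALSE)
  }
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "n_failed") <- sum(failed)
  out
}

#' Posterior mode and highest-density interval
#'
#' Summarizes a vector of posterior draws the way animal-model results are
#' usually reported: the mode of a Gaussian kernel density estimate
#' (Silverman's rule bandwidth by default) together with the shortest
#' interval containing a `level` fraction of the draws (the highest posterior
#' density interval).
#'
#' @param x Numeric vector of posterior draws (at least 2 finite values;
#'   `NA`s are dropped).
#' @param level Credible level (default 0.95).
#' @param bw Kernel bandwidth passed to [stats::density()]; default
#'   Silverman's rule (`"nrd0"`).
#' @return A list of class `posterior_summary` with `mode`, `ci_low`,
#'   `ci_high`, `level`.
#' @examples
#' summarize_posterior(rnorm(1000, 5))
#' @export
summarize_posterior <- function(x, level = 0.95, bw = "nrd0") {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least 2 finite values", call. = FALSE)
  stopifnot(level > 0, level < 1)
  if (diff(range(x)) == 0) {
    out <- list(mode = x[1L], ci_low = x[1L], ci_high = x[1L], level = level)
  } else {
    dens <- stats::density(x, bw = bw)
    ci <- hpd_interval(x, level = level)
    out <- list(mode = dens$x[which.max(dens$y)],
                ci_low = ci[1L], ci_high = ci[2L], level = level)
  }
  structure(out, class = "posterior_summary")
}

#' Shortest interval containing a given fraction of draws
#'
#' @param x Numeric vector of draws.
#' @param level Fraction of draws the interval must contain.
#' @return Length-2 numeric vector `c(low, high)`.
#' @export
hpd_interval <- function(x, level = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  stopifnot(n >= 2L, level > 0, level < 1)
  m <- max(1L, min(n - 1L, ceiling(level * n)))
  widths <- x[(m + 1L):n] - x[1L:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' @export
print.posterior_summary <- function(x, digits = 4, ...) {
  cat("Posterior mode ", signif(x$mode, digits), " (",
      100 * x$level, "% HPD: ", signif(x$ci_low, digits), " to ",
      signif(x$ci_high, digits), ")\n", sep = "")
  invisible(x)
}
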