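#' Truncation-selection experiment on a Poisson/log trait
#'
#' Configuration for one forward simulation of truncation selection: latent
#' values are drawn as \eqn{\mu + a + e} with \eqn{a \sim N(0, V_{A,\ell})}
#' and \eqn{e \sim N(0, V_{env})}, observed counts as Poisson of the
#' exponentiated latent value, and the individuals with the largest counts
#' are selected as parents (positive truncation selection).
#'
#' `mode` controls how offspring breeding values are formed:
#' \describe{
#'   \item{immediate}{midparent value plus segregational variance,
#'     \eqn{a_i \sim N((a_d + a_s)/2,\, V_{A,\ell}/2)}, parents non-inbred.
#'     The single-generation response, which carries the transient
#'     linkage-disequilibrium (Bulmer) reduction of latent variance.}
#'   \item{permanent}{breeding values redrawn around the selected parents'
#'     mean with the full parental-generation variance,
#'     \eqn{a_i \sim N(\bar a_{sel}, V_{A,\ell})}: the equilibrium response
#'     after the transient disequilibrium has decayed.}
#' }
#'
#' @param mu Latent intercept.
#' @param var_a Latent additive genetic variance.
#' @param var_env Remaining latent variance (environment + overdispersion).
#' @param prop_selected Proportion of parents selected, in (0, 1].
#' @param n_parents,n_offspring Population sizes (default 10000 each).
#' @param seed Optional RNG seed applied by [simulate_generation()].
#' @param mode `"immediate"` or `"permanent"`.
#' @return An object of class `selection_experiment`.
#' @export
selection_experiment <- function(mu, var_a, var_env, prop_selected,
                                 n_parents = 10000, n_offspring = 10000,
                                 seed = NULL,
                                 mode = c("immediate", "permanent")) {
  mode <- match.arg(mode)
  stopifnot(is.finite(mu), var_a >= 0, var_env >= 0,
            prop_selected > 0, prop_selected <= 1,
            n_parents >= 2, n_offspring >= 1)
  structure(list(mu = mu, var_a = var_a, var_env = var_env,
                 prop_selected = prop_selected,
                 n_parents = as.integer(n_parents),
                 n_offspring = as.integer(n_offspring),
                 seed = seed, mode = mode),
            class = "selection_experiment")
}

#' Simulate one generation of truncation selection
#'
#' Runs the experiment described by [selection_experiment()] and returns the
#' realized selection differentials and responses on both scales. Ties at
#' the truncation boundary are broken uniformly at random so the quota is hit
#' exactly. The latent response is the change in mean latent value between
#' the offspring and parental generations; the observed response the change
#' in mean count.
#'
#' @param exp A [selection_experiment()].
#' @return A list of class `selection_summary` with elements `s_lat`,
#'   `r_lat`, `s_obs`, `r_obs`, `h2_lat`, `h2_obs_theory`, `n_selected`.
#' @examples
#' ex <- selection_experiment(mu = 0, var_a = 0.05, var_env = 0.05,
#'                            prop_selected = 0.5, n_parents = 1000,
#'                            n_offspring = 1000, seed = 1)
#' simulate_generation(ex)$s_obs
#' @export
simulate_generation <- function(exp) {
  stopifnot(inherits(exp, "selection_experiment"))
  if (!is.null(exp$seed)) set.seed(exp$seed)
  n <- exp$n_parents
  a <- stats::rnorm(n, 0, sqrt(exp$var_a))
  e <- stats::rnorm(n, 0, sqrt(exp$var_env))
  lat <- exp$mu + a + e
  z <- stats::rpois(n, exp(lat))
  n_sel <- ceiling(exp$prop_selected * n)
  if (n_sel < 2) {
    stop("fewer than 2 selected parents: selection is degenerate",
         call. = FALSE)
  }
  # top counts first; random jitter breaks boundary ties to hit the quota
  sel <- order(z, stats::runif(n), decreasing = TRUE)[seq_len(n_sel)]
  m <- exp$n_offspring
  a_off <- if (exp$mode == "immediate") {
    dam <- sel[sample.int(n_sel, m, replace = TRUE)]
    sire <- sel[sample.int(n_sel, m, replace = TRUE)]
    stats::rnorm(m, (a[dam] + a[sire]) / 2, sqrt(exp$var_a / 2))
  } else {
    stats::rnorm(m, mean(a[sel]), sqrt(exp$var_a))
  }
  lat_off <- exp$mu + a_off + stats::rnorm(m, 0, sqrt(exp$var_env))
  z_off <- stats::rpois(m, exp(lat_off))
  v_lat <- exp$var_a + exp$var_env
  theory <- poisson_log_params(latent_model(exp$mu, var_a = exp$var_a,
                                            var_re = exp$var_env, var_o = 0,
                                            family = "poisson.log"))
  structure(list(
    s_lat = mean(lat[sel]) - mean(lat),
    r_lat = mean(lat_off) - mean(lat),
    s_obs = mean(z[sel]) - mean(z),
    r_obs = mean(z_off) - mean(z),
    h2_lat = if (v_lat > 0) exp$var_a / v_lat else NA_real_,
    h2_obs_theory = theory$h2_obs,
    n_selected = n_sel
  ), class = "selection_summary")
}

#' @export
print.selection_summary <- function(x, digits = 4, ...) {
  cat("One generation of truncation selection (", x$n_selected,
      " parents selected)\n", sep = "")
  cat("  latent   S = ", signif(x$s_lat, digits), ", R = ",
      signif(x$r_lat, digits), "\n", sep = "")
  cat("  observed S = ", signif(x$s_obs, digits), ", R = ",
      signif(x$r_obs, digits), "\n", sep = "")
  cat("  generating h2_lat = ", signif(x$h2_lat, digits),
      ", theoretical h2_obs = ", signif(x$h2_obs_theory, digits), "\n",
      sep = "")
  invisible(x)
}

#' Replicated truncation-selection scenarios
#'
#' Runs [simulate_generation()] `replicates` times for every scenario row and
#' averages the realized differentials and responses, with Monte-Carlo
#' standard errors. A single root seed makes the whole grid reproducible.
#'
#' @param scenarios Data frame with columns `h2_lat`, `mu`, `prop` (one row
#'   per scenario); latent phenotypic variance is `var_p_lat` in every cell,
#'   so `var_a = h2_lat * var_p_lat`.
#' @param replicates Number of replicate generations per scenario.
#' @param n_parents,n_offspring Population sizes per replicate.
#' @param var_p_lat Total latent phenotypic variance (default 0.1).
#' @param seed Root RNG seed.
#' @param mode Offspring breeding-value scheme, see [selection_experiment()].
#' @return A data frame, one row per scenario: the scenario columns plus
#'   means of `s_lat`, `r_lat`, `s_obs`, `r_obs`, the realized heritability
#'   ratios `ratio_lat` and `ratio_obs` (ratio of means), standard errors
#'   `se_ratio_lat`, `se_ratio_obs` and `se_r_obs`, and the generating-model
#'   values `h2_lat` and `h2_obs_theory`.
#' @export
replicate_grid <- function(scenarios, replicates, n_parents = 2000,
                           n_offspring = 2000, var_p_lat = 0.1, seed = NULL,
                           mode = c("immediate", "permanent")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(scenarios),
            all(c("h2_lat", "mu", "prop") %in% names(scenarios)))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    ex <- selection_experiment(
      mu = sc$mu, var_a = sc$h2_lat * var_p_lat,
      var_env = (1 - sc$h2_lat) * var_p_lat,
      prop_selected = sc$prop, n_parents = n_parents,
      n_offspring = n_offspring, mode = mode)
    reps <- replicate(replicates, unlist(simulate_generation(ex)))
    m <- rowMeans(reps)
    ratio_lat <- m["r_lat"] / m["s_lat"]
    ratio_obs <- m["r_obs"] / m["s_obs"]
    data.frame(
      h2_lat = sc$h2_lat, mu = sc$mu, prop = sc$prop,
      s_lat = m[["s_lat"]], r_lat = m[["r_lat"]],
      s_obs = m[["s_obs"]], r_obs = m[["r_obs"]],
      ratio_lat = ratio_lat,
      se_ratio_lat = stats::sd(reps["r_lat", ] / reps["s_lat", ]) /
        sqrt(replicates),
      ratio_obs = ratio_obs,
      se_ratio_obs = stats::sd(reps["r_obs", ] / reps["s_obs", ]) /
        sqrt(replicates),
      se_r_obs = stats::sd(reps["r_obs", ]) / sqrt(replicates),
      h2_obs_theory = m[["h2_obs_theory"]]
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Truncation selection expressed as a fitness function
#'
#' Bridges the simulator's selection rule to the prediction machinery: under
#' positive truncation selection keeping a proportion `prop_selected` of the
#' population, fitness is 0 below the threshold count, 1 above it, and equal
#' to the fraction of boundary individuals the quota admits at the threshold
#' itself. The threshold and boundary fraction are derived from the model's
#' marginal category probabilities, so [mean_fitness()] of the returned spec
#' equals `prop_selected`. Alternatively, a hard `threshold` may be given
#' directly (fitness 1 at and above it).
#'
#' @param model A [latent_model()] with a discrete family.
#' @param prop_selected Proportion selected, in (0, 1].
#' @param threshold Hard threshold count (used when `prop_selected` is
#'   missing).
#' @param nodes Gauss-Hermite nodes for the marginal category probabilities.
#' @return A [fitness_spec()] with attributes `threshold` and
#'   `boundary_fraction`.
#' @export
truncation_fitness <- function(model, prop_selected = NULL, threshold = NULL,
                               nodes = 64) {
  stopifnot(inherits(model, "latent_model"))
  if (!model$family$discrete) {
    stop("truncation_fitness applies to discrete families", call. = FALSE)
  }
  if (is.null(prop_selected)) {
    stopifnot(is.numeric(threshold), threshold >= 0)
    thr <- as.integer(threshold)
    frac <- 1
  } else {
    stopifnot(prop_selected > 0, prop_selected <= 1)
    pk <- marginal_category_probs(model, nodes = nodes)
    k <- seq_along(pk) - 1L
    tail_above <- rev(cumsum(rev(pk))) - pk  # P(Z > k)
    thr <- k[which(tail_above <= prop_selected)[1L]]
    frac <- (prop_selected - tail_above[thr + 1L]) / pk[thr + 1L]
    frac <- min(max(frac, 0), 1)
  }
  spec <- fitness_spec(fun = function(k) as.numeric(k > thr) +
                         frac * as.numeric(k == thr))
  attr(spec, "threshold") <- thr
  attr(spec, "boundary_fraction") <- frac
  spec
}

#' Marginal observed-scale category probabilities
#'
#' \eqn{P(Z = k)}: the conditional pmf integrated over the latent
#' distribution (averaged over fixed-effect predictions when present), for
#' `k` over the adaptively truncated support.
#'
#' @param model A [latent_model()] with a discrete family.
#' @param nodes Gauss-Hermite nodes.
#' @return Numeric vector of probabilities for categories `0:(length - 1)`.
#' @export
marginal_category_probs <- function(model, nodes = 64) {
  stopifnot(inherits(model, "latent_model"), model$family$discrete)
  hi <- max(latent_means(model)) + 10 * sqrt(model$total_var)
  kmax <- max(model$family$support(hi))
  vapply(0:kmax, function(k) {
    average_over_predictions(function(l) model$family$pmf(k, l), model,
                             nodes = nodes)
  }, numeric(1))
}
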