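---
title: "From latent GLMM parameters to data-scale quantitative genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From latent GLMM parameters to data-scale quantitative genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgscales)
```

## The three scales of a GLMM

A generalized linear mixed model for a non-Gaussian trait — survival,
clutch size, parasite counts — can be read as operating on three scales:

* the **latent scale** $\ell = \mu + X b + a + \dots + o$, on which all
  fixed and random effects (including the additive genetic effects $a$,
  with variance $V_{A,\ell}$, and an overdispersion residual $o$ with
  variance $V_O$) are additive and normally distributed;
* the **expected data scale** $\eta = g^{-1}(\ell)$, reached through the
  inverse link — the "intrinsic" trait value of an individual;
* the **observed data scale**, on which realized phenotypes $z$ scatter
  around $\eta$ according to the distribution function (Poisson, binomial,
  ...), contributing irreducible noise with conditional variance
  $v(\ell, \theta)$.

Variance components are estimated on the latent scale, but selection acts —
and comparative questions are usually posed — on the data scales. Because
the link is nonlinear, converting between scales is not a matter of
transforming point estimates: every data-scale parameter is an expectation
over the full latent distribution. This package implements those
conversions, together with selection-response prediction routed through the
latent scale, for the families `gaussian.identity`, `poisson.log`,
`binomial.logit`, `binomial.probit` and `negbin.log`.

All inputs are plain numbers from a fitted model: the package deliberately
fits nothing itself, and no raw phenotypes or pedigrees are consumed.

## Data-scale parameters

Writing $f_N(\ell; m, V)$ for a normal density and
$V = V_{A,\ell} + V_{RE} + V_O$ for the total latent variance, the
population mean and the two phenotypic variances are

$$\bar z = \int g^{-1}(\ell)\, f_N(\ell; \mu, V)\, d\ell, \qquad
  V_{P,exp} = \int \left(g^{-1}(\ell) - \bar z\right)^2 f_N\, d\ell, \qquad
  V_{P,obs} = V_{P,exp} + \int v(\ell, \theta)\, f_N\, d\ell .$$

The mean is the same on both data scales; the variances are not, and the
distinction matters biologically: $V_{P,obs} - V_{P,exp}$ is noise that no
amount of genetic or environmental explanation can remove.

Genotypic values are conditional means given the latent genetic value,
$E[z \mid a] = \int g^{-1}(\ell) f_N(\ell; \mu + a, V_{RE} + V_O)\, d\ell$,
and their variance over $a \sim N(0, V_{A,\ell})$ (an outer quadrature) is
the total genotypic variance — additive plus the non-additive variance the
nonlinear link manufactures out of purely additive latent variation.

The strictly additive part follows from Stein's lemma: the least-squares
slope of phenotype on latent breeding value is the *average derivative of
the inverse link*,

$$\Psi = E\!\left[\frac{dg^{-1}}{d\ell}\right], \qquad
  V_{A,obs} = V_{A,exp} = \Psi^2\, V_{A,\ell}.$$

From these, `qg_params()` assembles heritabilities on all three scales
($h^2_{lat} = V_{A,\ell}/V$, $h^2_{exp} = V_{A,obs}/V_{P,exp}$,
$h^2_{obs} = V_{A,obs}/V_{P,obs}$, and broad-sense
$H^2_{obs} = V(E[z|a])/V_{P,obs}$), the additive coefficient of variation
$CV_A = 100\sqrt{V_{A,obs}}/\bar z$ and the evolvability
$I_A = V_{A,obs}/\bar z^2$. We adopt the square-root (Houle-convention)
$CV_A$; a mean-standardized variance without the root is $I_A$'s job. When
$\bar z$ is numerically zero the standardized measures are reported as `NA`
with a warning rather than as infinities.

```{r}
m <- latent_model(mu = 0, var_a = 0.5, var_o = 0, family = "poisson.log")
qg_params(m)
```

This worked scenario is instructive: of the observed variance 2.35, only
1.07 lies in expected values. Even with the entire latent variance
additive, $H^2_{obs}$ here is 0.454 and can never exceed 0.5 — more than
half the measured variance is irreducible Poisson noise.

## Fixed effects

Because the link is nonlinear, fixed effects do not simply shift data-scale
parameters: means, variances, and even $V_{A,obs}$ depend on the intercept,
which is an arbitrary software convention. The remedy is marginalization.
Given predicted latent values $\hat\ell_i = X\hat b$ (supply any subset of
effects: it is legitimate to integrate over biologically meaningful
covariates while fixing nuisance corrections at a reference value), every
expectation is averaged across $N(\mu + \hat\ell_i, V)$ kernels, with a
single grand mean used inside the variance integrals. The result is
invariant to reparameterizations that move a constant between the intercept
and the predictions — a property the test suite checks explicitly. When the
sampled covariates are unrepresentative, `covariate_distribution()` accepts
representative predicted values, a sampler with coefficients, or a
univariate density, and `integrate_over_covariates()` performs the double
integral.

## Closed forms and their role as oracles

Two families admit exact analytic solutions, used both as fast paths and as
independent checks on the quadrature engine.

**Binomial(1)/probit** is exactly the threshold (liability) model. The
liability scale is the latent scale plus the probit *link variance*
$V_L = 1$, so $h^2_{liab} = V_{A,\ell}/(V + 1)$, and the Dempster–Lerner
transformation $h^2_{obs} = t^2 h^2_{liab} / (p(1-p))$ — with $p$ the
probability of occurrence and $t$ the standard normal density at its
quantile — reproduces the generic $\Psi$ route exactly
(`threshold_params()`). It is specific to the probit link; logit models go
through the numerical route.

**Poisson/log** has $\Psi$ and $v$ both equal to the expected value, giving
$\lambda = e^{\mu + V/2}$, $V_{P,exp} = \lambda^2(e^V - 1)$,
$V_{P,obs} = V_{P,exp} + \lambda$, $V_{A,obs} = \lambda^2 V_{A,\ell}$ and
$V(E[z|a]) = \lambda^2(e^{V_{A,\ell}} - 1)$ (`poisson_log_params()`;
`qg_params()` dispatches to it automatically unless `closed_form = "off"`).
$h^2_{obs}$ and $H^2_{obs}$ converge as $V_{A,\ell} \to 0$.

The negative binomial is supported through the generic numerical route
only, with its mean--dispersion parameterization
($\mathrm{var} = \lambda + \lambda^2/\theta$).

## Multivariate extension

For multiresponse models, the vector-valued inverse link acts elementwise,
so its Jacobian is diagonal and
$G_{obs} = \Psi\, G_\ell\, \Psi^T$ with $\Psi$ the diagonal matrix of
per-trait average derivatives (`g_observed()`). Genetic correlations are
therefore unchanged by the scale conversion. Phenotypic covariance entries
depend only on *bivariate* latent marginals, so `mv_phen_cov()` evaluates
each pair by two-dimensional tensor-product Gauss–Hermite quadrature —
exact for any number of traits, which is why no Monte-Carlo fallback is
needed for these operations. On the observed scale the distribution noise
is taken to be conditionally independent across traits given the latent
values (the standard multiresponse GLMM assumption), so it enters the
diagonal only; trait pairs whose observation noise is correlated by the
measurement process violate this and are out of scope.

## Predicting the response to selection

Data-scale breeding values and phenotypes are not jointly Gaussian, so the
breeder's equation applied on the observed scale is only approximate. On
the latent scale its assumptions hold by construction. Given fitness
$W_P(k)$ per observed category (`fitness_spec()`, as a table or a
function), the chain is

$$W_{exp}(\ell) = \sum_k W_P(k) P(Z = k \mid \ell), \qquad
  \bar W = E[W_{exp}(\ell)], \qquad
  \Delta\mu = V_{A,\ell}\, E\!\left[\tfrac{dW_{exp}}{d\ell}\right]
  \frac{1}{\bar W},$$

again via Stein's lemma, and the data-scale response recomputes the
population mean with the latent mean (and every fixed-effect prediction)
shifted by $\Delta\mu$:
$\Delta\bar z = \int g^{-1}(\ell) f_N(\ell; \mu + \Delta\mu, V) d\ell - \bar z$
(`data_scale_response()`). The derivative of $W_{exp}$ is computed
analytically through the family's score function
(e.g. $(k - \lambda)$ for Poisson/log); only Gaussian fitness functions
fall back to central finite differences (step $10^{-4}$ latent SD). Only
relative fitness matters: rescaling $W$ changes nothing.

Two caveats are deliberate. First, the prediction is the **permanent**
response: directional selection also causes a transient
linkage-disequilibrium (Bulmer) reduction of latent variance, which the
nonlinear link converts into a transient shortfall of the first-generation
mean — we do not model it, and the simulator's "immediate" mode exists
precisely to show the gap. Second, the multivariate gradient version of
$\Delta\mu$ is not implemented; only univariate selection is predicted.

## The simulation study

`simulate_generation()` and `replicate_grid()` reproduce, at desk scale,
the validation design for these predictions: parents receive latent values
$\mu + a + e$, counts are Poisson of the exponentiated latent value, the
top fraction by count is selected (ties at the boundary broken uniformly at
random so the quota is met exactly — the bridge `truncation_fitness()`
mirrors this by giving the boundary category fractional fitness, so mean
fitness equals the selected proportion). Dams and sires are drawn with
replacement from the selected pool; offspring breeding values are midparent
plus segregational variance $V_{A,\ell}/2$ (non-inbred parents) in
immediate mode, or redrawn around the selected parents' mean with the full
parental variance in permanent mode.

The default study conditions mirror the validation design: latent
phenotypic variance 0.1, latent heritabilities
$\{0.1, 0.3, 0.5, 0.8\}$, latent means at the integers 0–3, and selected
proportions $\{0.2, 0.5, 0.8\}$ spanning strong to weak selection. For
routine testing we run 200 replicates of 2,000 parents and 2,000 offspring
per cell: Monte-Carlo standard errors scale as $1/\sqrt{\text{replicates}}$,
and at this size the latent-scale breeder's-equation check resolves the
generating heritability to about $\pm 0.02$ per cell.

Two properties are checked against this simulator: the realized latent
heritability $\bar r_{lat}/\bar s_{lat}$ equals the generating $h^2_{lat}$
(the breeder's equation is *exact* on the latent scale, because selecting
on counts maps to the latent scale through a linear conditional
expectation), and the permanent-mode observed response equals
$\Delta\bar z$ from the prediction chain. On the observed scale, by
contrast, realized heritability deviates from $h^2_{obs}$ under strong
selection — that mismatch is the motivation for predicting through the
latent scale.

A note on test design: a grid of 48 cells each required to sit within
3 Monte-Carlo SE has, even under a perfect match, roughly a 12% chance
that some cell strays outside by multiplicity alone. The grid checks are
therefore two-stage sequential tests: cells flagged at stage 1 are
re-simulated independently with ten-fold more replicates and must fall
within 3 SE there. The tolerance is identical at both stages; the second
stage only separates systematic error from the fluctuations a single-stage
rule cannot.

What the simulator does *not* emulate about real data: pedigree structure
(parents are unrelated and non-inbred, so segregational variance is exactly
$V_{A,\ell}/2$), fixed effects, overdispersion beyond the latent
environmental term, multiple generations, and any Bulmer recursion of the
variance. Passing these tests validates the conversion and prediction
machinery under the model's own assumptions; it says nothing about model
misspecification on real data.

## Posterior uncertainty

Bayesian animal-model output arrives as posterior samples of
$(\mu, V_{A,\ell}, V_{RE}, V_O)$. `map_posterior()` applies any
computation row-wise (failing rows are flagged `NA`, counted and warned
about, never fatal), and `summarize_posterior()` reports the conventional
summary: a Gaussian-KDE posterior mode (Silverman's rule bandwidth,
overridable) with a 95% highest-posterior-density interval (shortest
covering window; equal-tailed intervals are deliberately not the default).
Fixed-effect predictions can be shared across samples (point-estimate
predictions) or supplied per sample; both are legitimate, and they answer
slightly different questions about what is held fixed under the posterior.

## Numerical choices

* **Quadrature.** Gauss–Hermite with 64 nodes by default (`nodes`
  argument everywhere); integrands are smooth link transforms against a
  Gaussian kernel, for which 64 nodes deliver relative error below
  $10^{-8}$ on all supported families over total latent variances up to 5.
  The tests cross-check against closed forms and a trapezoid rule on
  $\pm 12$ SD.
* **Zero variance** is treated as a point mass — no division by a zero SD.
* **Count-support truncation** is adaptive: mean plus 12 conditional SD,
  never below 50; the heavier-tailed negative binomial additionally takes
  an upper quantile bound. `pmf_moments()` refuses to report moments if
  the captured mass falls below $1 - 10^{-12}$.
* **Identifiability.** $V_O$ is a required argument, never defaulted: for
  binary data it is unobservable and conventionally fixed (commonly to 1
  in probit/logit analyses), and that convention must be the caller's
  explicit choice.
* **Fitness edge cases.** Categories a fitness table does not cover are an
  error if they carry more than $10^{-8}$ of latent-weighted probability
  mass; a mean fitness that is positive only through quadrature-tail
  underflow (fitness concentrated on unreachable categories) triggers an
  undefined-selection error rather than a nonsense ratio.
* **PSD hygiene.** Multivariate covariance outputs that leave the positive
  semidefinite cone by numerical error are eigenvalue-clipped back, with a
  warning and a `projected` attribute.

## Limitations

No GLMM fitting, no pedigree/relatedness construction, no multinomial or
zero-inflated families, no analytic logit approximations, no
negative-binomial closed forms, no Bulmer dynamics, no multivariate
selection gradients. The command-line front end
(`inst/cli/qgscales.R`) is a thin wrapper over the exported functions for
shell pipelines; the R API is the primary interface.
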