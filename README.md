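# qgscales

Quantitative genetic parameters on the data scales from GLMM output, and
selection-response prediction through the latent scale.

## The problem

Generalized linear mixed models — in particular the generalized animal
model — are the standard tool for estimating additive genetic variance in
non-Gaussian traits such as survival, clutch size or parasite counts. But
the variance components they return live on a *latent* scale, while
selection acts and biology is discussed on the scale of the measured trait.
Because the link function is nonlinear, the conversion is not a
transformation of point estimates: every data-scale quantity is an
expectation over the whole latent distribution, and fixed effects (even an
arbitrary intercept choice) leak into every variance component.

`qgscales` takes plain numbers from a fitted GLMM — intercept $\mu$,
latent additive variance $V_{A,\ell}$, other random-effect variances
$V_{RE}$, overdispersion $V_O$, optionally predicted values $X\hat b$ or a
table of posterior samples — and computes, for the families
gaussian/identity, Poisson/log, binomial/logit, binomial/probit and
negative-binomial/log:

- the data-scale mean $\bar z$ and phenotypic variances $V_{P,exp}$ and
  $V_{P,obs}$ (the latter adding the distribution noise
  $E[v(\ell,\theta)]$);
- genotypic values/variance, and the additive genetic variance
  $V_{A,obs} = \Psi^2 V_{A,\ell}$, where
  $\Psi = E[dg^{-1}/d\ell]$ is the average inverse-link derivative
  (Stein's lemma);
- heritabilities on all three scales, broad-sense $H^2_{obs}$, $CV_A$ and
  evolvability $I_A$;
- multivariate analogues, including $G_{obs} = \Psi G_\ell \Psi^T$;
- exact closed forms for Poisson/log and for the binomial/probit threshold
  (liability) model (Dempster–Lerner), used as fast paths and as oracles
  for the generic quadrature engine;
- the expected response to selection, routed through the latent scale:
  $W_{exp}(\ell) = \sum_k W_P(k)P(Z{=}k|\ell)$,
  $\Delta\mu = V_{A,\ell} E[dW_{exp}/d\ell]/\bar W$, and the data-scale
  response $\Delta\bar z$;
- a forward simulator of truncation selection on a Poisson/log trait that
  validates those predictions (immediate vs. permanent response);
- posterior batching with mode + 95% HPD summaries.

It fits nothing itself and consumes no raw data — it is a post-processing
companion to whatever fitted the model.

## Worked example

A count trait, log link, with latent intercept 0.5 and latent variances
$V_{A,\ell}=0.2$, $V_{RE}=0.1$, $V_O=0.1$:

```r
library(qgscales)
m <- latent_model(mu = 0.5, var_a = 0.2, var_re = 0.1, var_o = 0.1,
                  family = "poisson.log")
qg_params(m)
#> Quantitative genetic parameters on the data scales (closed_form)
#> Phenotypic mean (z-bar)                        2.014
#> Phenotypic variance, expected scale (V_P,exp)  1.994
#> Phenotypic variance, observed scale (V_P,obs)  4.008
#> Total genotypic variance                       0.8978
#> Psi (mean inverse-link derivative)             2.014
#> Additive genetic variance (V_A,obs)            0.811
#> Heritability, latent scale (h2_lat)            0.5
#> Heritability, expected scale (h2_exp)          0.4066
#> Heritability, observed scale (h2_obs)          0.2023
#> Broad-sense heritability (H2_obs)              0.224
#> Additive CV (CV_A, %)                          44.72
#> Evolvability (I_A)                             0.2
```

Half the latent variance is additive ($h^2_{lat} = 0.5$), yet on the
observed scale heritability is 0.20: the mean count is about 2, so roughly
half of $V_{P,obs}$ (2.01 of 4.01) is irreducible Poisson noise, and the
log link converts part of the additive latent variance into non-additive
genotypic variance ($V_{A,obs} = 0.81$ of a genotypic 0.90).

Truncation selection keeping the top 30% of counts:

```r
data_scale_response(m, truncation_fitness(m, prop_selected = 0.3))
#> Predicted response to selection (via the latent scale)
#>   mean fitness W-bar:        0.3
#>   latent response d-mu:      0.2543
#>   data-scale response d-z:   0.5831
```

Mean fitness equals the selected proportion (the boundary count category
gets fractional fitness to meet the quota exactly); the predicted permanent
response is +0.58 counts. A binary trait goes through the exact threshold
model instead:

```r
threshold_params(latent_model(0.8, var_a = 0.9, var_re = 0.5, var_o = 1,
                              family = "binomial.probit"))
#> Threshold (liability) model parameters
#>   h2 on the liability scale: 0.2647
#>   link variance V_L:         1
#>   p (minor phenotype):       0.3322
#>   t = dnorm(qnorm(p)):       0.3631
#>   h2 on the observed scale:  0.1573
```

A thin command-line wrapper over the same functions ships in
`inst/cli/qgscales.R`:

```sh
Rscript inst/cli/qgscales.R params --family poisson.log \
    --mu 0 --var-a 0.5 --var-o 0
```

See `vignettes/scale-conversion.Rmd` for the model, the assumptions, and
every numerical choice.

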