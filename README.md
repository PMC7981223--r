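# grouseRSF

Multi-scale Bayesian resource selection functions (RSFs) for seasonal
wildlife habitat mapping, built around the analysis design used for
translocated greater sage-grouse: use–availability logistic regression with
Bayesian Lasso shrinkage, latent-indicator selection of the spatial scale at
which habitat covariates act, calibration-based out-of-sample validation,
and raster products — seasonal habitat surfaces, an annual composite, and
habitat-change maps between vegetation epochs.

It is written for quantitative wildlife ecologists who have telemetry
locations and covariate rasters and want a tested, reproducible pipeline
from raw locations to habitat maps, and for methodologists who want the
Bayesian machinery (Laplace priors with the exact conjugate Gibbs update of
the shrinkage parameter, categorical-Gibbs scale indicators, per-individual
random intercepts) exposed as individually testable functions.

## The model

Used locations ($y=1$) are contrasted with available background points
($y=0$, five per used point, uniform in the minimum convex polygon of the
used locations) through a Bernoulli logistic model

$$g(x) = \beta_0 + \beta_1 x_{1} + \dots + \beta_k x_{k} + \gamma_j,
\qquad \gamma_j \sim N(0, \sigma_\gamma^2),$$

with Laplace (Lasso) priors on the $\beta_k$, a Gamma hyperprior on the
shrinkage parameter $\lambda$ (updated by its exact Gibbs conditional
Gamma$(a+K,\, b+\sum|\beta_k|)$), and a latent categorical indicator per
multi-scale covariate choosing the focal-smoothing radius whose column
carries that covariate's coefficient. The RSF is the intercept-free
exponential $\hat w(x) = \exp(\sum_k \hat\beta_k x_k)$, a relative index of
selection. Fitting is two-stage — scale selection, then a refit at the
modal radii — by adaptive random-walk Metropolis (3 chains × 30,000
iterations, 15,000 burn-in, thinned by 5; Gelman–Rubin $\hat r < 1.05$
required of every parameter). Held-out validation bins test-availability
$\hat w$ into 10 quantile bins and compares observed with expected used
counts (slope, $R^2$, Spearman), escalating quadratic terms while the
statistics miss the 0.75 / [0.8, 1.2] thresholds; used-habitat calibration
(UHC) envelopes diagnose per-covariate misfit.

Everything runs against a synthetic landscape-and-telemetry generator with
known truth, so the whole pipeline is testable offline; see the methods
vignette (`vignettes/multiscale-bayesian-rsf.Rmd`) for the science and the
design decisions.

## A worked example

Simulate the standard synthetic study (120×120-cell landscape, 30
individuals, ~150 used points at 5:1 availability), fit the two-stage model
on two thirds of the individuals at a reduced chain profile, and validate
on the withheld third:

```r
library(grouseRSF)
b <- benchmark_calibration(seed = 2, iterations = 5000, burn_in = 2500)
b$calibration
#> <rsf_calibration> 10 bins, 50 used: slope 1.141, R^2 0.975, Spearman 0.789
b$two_stage$scale_posterior
#>     variable         column radius  prob modal
#> 1      shrub       shrub@60     60 0.204 FALSE
#> 2      shrub      shrub@331    331 0.352 FALSE
#> 3      shrub      shrub@887    887 0.444  TRUE
#> 4 ruggedness  ruggedness@60     60 0.002 FALSE
#> 5 ruggedness ruggedness@331    331 0.012 FALSE
#> 6 ruggedness ruggedness@887    887 0.986  TRUE
round(posterior_summary(b$two_stage$fit), 2)["release", ]
#>         mean median lo68 hi68 lo95 hi95
#> release 1.02   1.01 0.88 1.17 0.76  1.3
```

The calibration line says the fitted model's expected used counts track the
observed counts of birds it never saw (slope near 1, high rank
correlation); the scale posterior concentrates on the 887 m radius that
generated the data; and the release-site attraction coefficient (truth 1.0)
is recovered with its credible interval. The full pipeline — all three
seasons, habitat surfaces, the annual composite, shrub-epoch change maps
and the resident/translocated contrast — runs from one config:

```r
res <- run_rsf_pipeline(default_pipeline_config(seed = 1), outdir = "out")
```

writing locations, designs, posterior and scale summaries, calibration
tables (CSV), boundaries (GeoJSON), and surfaces (ESRI ASCII grid) under
`out/`.

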