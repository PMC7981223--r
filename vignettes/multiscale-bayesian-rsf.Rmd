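---
title: "Multi-scale Bayesian resource selection: models, priors and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale Bayesian resource selection: models, priors and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`grouseRSF` estimates seasonal habitat selection of telemetered animals —
its running example is a translocated sage-grouse population — with
use–availability resource selection functions (RSFs), and turns the fitted
models into habitat surfaces and habitat-change maps. This vignette explains
the models, the priors, the validation machinery, and the design decisions a
user should understand before trusting output.

## The use–availability model

Telemetry locations (used points, $y = 1$) are contrasted against random
background points (available, $y = 0$) sampled uniformly inside the study
boundary, a minimum convex polygon (MCP) of the used locations. Five
available points are drawn per used point: enough to cover the availability
domain without inflating apparent precision through an enormous pseudo-sample.

The observation model is Bernoulli logistic,

$$g(x) = \beta_0 + \beta_1 x_{1i} + \dots + \beta_k x_{ki} \; (+\, \gamma_j),$$

with a per-individual random intercept $\gamma_j \sim N(0, \sigma_\gamma^2)$
for brood-rearing and summer data, where individuals contribute repeated
daily locations (thinned to one fix per day; individuals with fewer than 5
brood or 10 summer locations are dropped). Nests are single points and get
no random effect. The RSF itself discards the intercept:

$$\hat w(x) = \exp(\hat\beta_1 x_1 + \dots + \hat\beta_k x_k),$$

a *relative* index of selection — never an absolute probability of use.

## Covariates

* **Terrain**: elevation; ruggedness (TRI — the root of summed squared
  elevation differences to the eight neighbours), log-transformed as
  $\log(\mathrm{TRI} + 1)$ so flat cells map to 0; aspect enters as
  *northness* ($\cos$ of the downslope direction, in $[-1, 1]$) because a
  raw circular degree cannot enter a linear predictor coherently; slope is
  computed but expected to fall to the $|r| > 0.7$ Pearson collinearity
  screen against ruggedness and elevation, which rank above it in the
  screen's priority order.
* **Vegetation**: percent shrub cover, focal-averaged within a circular
  moving window (cell centres within the radius; the centre cell always
  included; the window shrinks at edges and nodata).
* **Distances**: roads, waterways, mesic-area centres and the translocation
  release site enter as exponential decays $\exp(-d/\alpha)$, with
  $\alpha$ = mean distance at used locations, capped at 6,400 m. The decay
  keeps far-field cells from dominating a linear distance term.

Shrub and ruggedness are *multi-scale*: the radius at which they act is
unknown, so one column per candidate radius is built. Candidate radii
derive from movements — the averages over individuals of each individual's
minimum, mean and maximum daily step (rounded to the metre, half up), with
an extra half-maximum radius for the wide-ranging summer season — or can be
fixed to the study's values (60/331/887 m for nesting and brood rearing;
111/767/1,503/3,005 m for summer).

All covariates are standardized to mean 0, SD 1 (sample SD, $n-1$) using
statistics from the *training* rows only; the stored scaling record is
reapplied verbatim to test rows and prediction rasters, so no information
leaks from held-out data into the transform.

## Priors and the sampler

Coefficients carry Laplace (double-exponential) shrinkage priors — the
Bayesian Lasso — guarding against overfitting at the small effective sample
sizes typical of translocation studies. The shrinkage parameter $\lambda$
gets a Gamma(0.01, 0.01) hyperprior; under $K$ Laplace priors its full
conditional is exactly Gamma$(0.01 + K,\; 0.01 + \sum_k |\beta_k|)$ and is
sampled by Gibbs. The intercept is excluded from the Lasso (it is discarded
for the RSF anyway) and gets a diffuse Normal(0, $10^2$) prior;
$\sigma_\gamma$ gets Uniform(0, 10) on the SD scale.

Sampling is single-site adaptive random-walk Metropolis (implemented in
C++), with per-parameter step sizes tuned towards 0.44 acceptance in
batches of 50 iterations *during burn-in only*, so the retained chain is a
fixed-kernel Markov chain. The default protocol is 3 chains × 30,000
iterations after a 15,000 burn-in, thinned to every 5th draw (9,000
retained draws); tests use a reduced 3 × 5,000 profile. Convergence is
checked with Gelman–Rubin $\hat r$ ($W$ = mean within-chain variance,
$B/n$ = variance of chain means, $\hat r = \sqrt{(((n-1)/n)W + B/n)/W}$)
against the 1.05 bound for every coefficient, $\lambda$ and
$\sigma_\gamma$; a failed check flags the fit, never silently passes.

### Scale selection

Which radius a multi-scale covariate acts at is itself a parameter: a
latent categorical indicator per variable selects, at each iteration, which
candidate column carries that variable's (shared) coefficient. The
indicator's full conditional is categorical with probabilities proportional
to the likelihood of each candidate column, under a uniform prior — the
standard latent-indicator construction of Bayesian scale selection. Because
the coefficient is shared and dimensions never change, this is an ordinary
Gibbs step; no cross-dimension proposal machinery is needed. Posterior
indicator frequencies estimate the scale probabilities. Fitting is
two-stage: stage 1 samples the indicators; stage 2 refits with each
variable fixed at its modal radius, and all downstream products (surfaces,
change maps) use the stage-2 model.

## Validation

Discrimination metrics (AUC) are avoided: available points are not
absences, so the model's job is *calibration* — predicting the relative
intensity of use. The held-out check bins the test-availability $\hat w$
values into 10 quantile bins; expected used counts per bin are
$n_{used} \cdot \sum_b \hat w / \sum \hat w$, observed counts come from the
withheld individuals, and the summary is the slope and $R^2$ of the
observed-on-expected regression (intercept included; a through-origin slope
is also reported) plus the Spearman correlation of observed counts with bin
rank. A well-calibrated model has slope near 1 and high correlation; the
escalation rule adds the square of the not-yet-squared predictor with the
largest absolute posterior mean, refits and revalidates while Spearman or
$R^2$ is ≤ 0.75 or the slope leaves [0.8, 1.2], stopping when predictors
are exhausted (a reported outcome, not an error). Validation predictions
keep the release-site decay term: held-out birds really do cluster near the
release site, and a deliberately amputated predictor would miscalibrate the
check by construction. The term is dropped only from spatial habitat maps,
where it is a nuisance of the translocation rather than habitat.

Used-habitat calibration (UHC) plots diagnose *which* covariate misfits:
for each posterior draw, test-availability points are resampled weighted by
that draw's $\hat w$, and the kernel density of the covariate over the
resample contributes one replicate curve (Gaussian kernel, Silverman
bandwidth fixed from the availability values, 512-point grid spanning the
pooled 0.5–99.5 percentiles). The envelope is the pointwise 2.5–97.5
percentile band. A caution learned from simulation: because the band is
pointwise and all replicates share the finite availability pool, the
whole-curve coverage fraction of even a *correct* model is a random
quantity averaging roughly 0.9 (range ~0.74–1.0 in our experiments at 150
used / 750 available points), while a model missing the true driver covers
only ~0.05–0.17 of that covariate's curve. Read UHC output as a contrast
between covariates, not against a hard 95% line.

## Habitat surfaces and change maps

Stage-2 coefficients (posterior means) are pushed over the covariate
rasters — decay-transformed with the training alphas and standardized with
the training scaling — omitting the intercept, random intercepts and the
release-site decay. The raster predictions agree with tabular `predict_w()`
to 1e-9 at the design points (tested). Each seasonal $w$ surface is mapped
to $(0,1)$ by the logistic transform $p = w/(1+w)$ — the intercept-free
form, chosen because the use–availability intercept reflects the sampling
ratio rather than habitat and is discarded from the RSF — and the annual
composite is the cellwise geometric mean of the three seasonal $p$
surfaces. Habitat change between shrub epochs recomputes the surface with
the early-epoch shrub layer — smoothed at the *selected* scale, all other
layers held fixed — and differences the logistic surfaces:
$\Delta = p_{late} - p_{early} \in (-1, 1)$. Swapping epochs negates
$\Delta$ exactly. The change map reflects changed *availability* under
fixed selection, not a change in selection behaviour. Mean $\Delta$ within
quantile classes of $p$ summarizes where losses concentrate.

## The synthetic study

Because the real geospatial layers and telemetry are not redistributable,
the package ships a generator that emulates them with known truth, and the
whole pipeline is exercised against it.

* **Landscape**: 120 × 120 cells of 30 m. Percent shrub cover is smoothed
  white noise (circular moving-average, 300 m range, variance restored
  after smoothing) with mean 9% and SD 5%, clipped to [0, 100] — the low
  cover typical of a range-fringe prairie site. Elevation is a 950 m base
  plus 25 m-SD smoothed relief and a gentle regional tilt so aspect and
  slope are non-degenerate. One road, one meandering stream, two mesic
  centres and a central release site are placed per seed.
* **Truth**: standardized selection coefficients shrub +0.8 (at 887 m),
  ruggedness −0.6 (887 m), elevation −0.4, northness +0.2, road −0.3,
  water −0.2, mesic +0.4, release-site decay +1.0, random-intercept SD
  0.3 — the qualitative pattern of the study system (strong shrub and
  release-site selection, avoidance of rugged ground and roads). The
  summer truth moves the scales to 1,503/767 m and nearly removes the
  release effect, as observed for the post-breeding season.
* **Telemetry**: daily locations are independent draws of raster cells
  with probability ∝ $\exp(x'\beta + \gamma_j)$, jittered uniformly within
  the cell. There is no movement kernel — the models condition on habitat
  only — but consecutive-day step distances still exist and feed the
  radius rule. Two shrub epochs differ by a smooth Wendland-bump deficit
  (default 6% peak, 1,000 m radius) centred on the release site.

What passing tests on this generator do **not** show: robustness to GPS
fix error, duty-cycle gaps, detection failure, serially correlated
movement, or habitat measured with error. The generator is deliberately
clean so that failures indict the estimator, not the data.

### Problem sizes and stochastic behaviour

The standard benchmark — 30 individuals × 5 daily locations (~150 used,
750 available rows), two-stage fit on 2/3 of individuals — was chosen to
mirror a realistic translocation cohort while keeping the full 3 × 30,000
protocol under a minute of compute. At these sizes the held-out
calibration uses ~50 used points, and its statistics are honestly noisy:
across seeds the slope's 5–95% range is roughly 0.5–1.4 around a median
near 1, and Spearman's median is ~0.8. Single-seed excursions below the
thresholds are sampling noise, not miscalibration — the same design with
thousands of points gives slope 1.007, $R^2$ 0.997, Spearman 1.0. The test
suite therefore asserts the medians of five seeded replicates against the
thresholds, and `scripts/acceptance.R` reports the single-run statistics
at the requested seed.

## Numerical choices

* Circular windows: membership by cell-centre distance; centre always in;
  radius below the cell size is the identity.
* TRI at borders uses the neighbours that exist; Horn gradients replicate
  edge cells, so border aspect keeps its sign but attenuates its magnitude.
* Quantile bins collapsing under tied $\hat w$ values are merged with a
  warning; fully constant $\hat w$ degenerates to a single bin with NA
  regression statistics.
* Constant covariate columns (e.g. a focal radius wider than the study
  area) are dropped from the design with a message rather than poisoning
  the standardization.
* Rounding of candidate radii is to the nearest metre, half up.
* Availability sampling is rejection sampling from the MCP bounding box;
  each block of 5 available points inherits the sampling unit of its paired
  used point, which keeps the 5:1 ratio exact within every train/test
  partition and makes unit-level splits leak-free.
* Seeds: every generator and sampler takes an explicit seed; chain $c$
  uses `seed + c - 1`; the pipeline fans a single global seed into fixed
  per-season, per-stage offsets.

## Known limitations

* Availability is uniform-in-MCP; step-selection or temporally matched
  availability designs are out of scope.
* The mesic distance is to polygon centroids, not edges.
* No spatial autocorrelation in residuals is modelled; the 5:1 design and
  one-per-day thinning are the only defences.
* The logistic transform of $w$ is a monotone convenience for compositing,
  not a probability of use.

## A worked run

```{r}
library(grouseRSF)

cfg <- default_pipeline_config(seed = 1,
                               model = rsf_model_config(chains = 3,
                                                        iterations = 5000,
                                                        burn_in = 2500))
res <- run_rsf_pipeline(cfg, outdir = "rsf-demo")

res$seasons$brood$calibration       # held-out calibration statistics
res$seasons$brood$two_stage$scale_posterior  # scale probabilities
res$contrast                        # resident vs translocated contrast
plot(res$seasons$brood$calibration)
```
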