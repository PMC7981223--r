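Package: grouseRSF
Title: Multi-Scale Bayesian Resource Selection Functions for Seasonal
    Habitat Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits use-availability resource selection functions (RSFs) for
    telemetry studies in a Bayesian framework with Laplace (Lasso) shrinkage
    priors, a conjugate Gibbs update for the shrinkage parameter, optional
    per-individual random intercepts, and latent-indicator selection of the
    spatial scale (focal-smoothing radius) at which multi-scale habitat
    covariates act. Provides the full supporting pipeline: synthetic landscape
    and telemetry simulation with known truth, terrain and distance-decay
    covariate engineering, minimum-convex-polygon availability sampling,
    quantile-bin calibration and used-habitat calibration (UHC) validation,
    quadratic-term escalation, seasonal and annual-composite habitat surfaces,
    and epoch-difference habitat-change maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    mgcv,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
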