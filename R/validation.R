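#' RSF predictions for covariate rows
#'
#' `w(x) = exp(sum beta_k x_k)` at the posterior coefficient means, with the
#' intercept always excluded and any terms in `drop_terms` (the release-site
#' nuisance decay, random intercepts) masked out. Rows must already be on
#' the standardized scale of the training fit.
#'
#' @param fit an `rsf_posterior` (or a named coefficient vector).
#' @param rows data frame of standardized covariate columns.
#' @param drop_terms coefficient names excluded from the linear predictor.
#' @return Positive numeric vector of relative selection values.
#' @export
predict_w <- function(fit, rows, drop_terms = character(0)) {
  beta <- if (inherits(fit, "rsf_posterior")) {
    m <- as.matrix(fit)
    colMeans(m[, fit$coef_names, drop = FALSE])
  } else fit
  beta <- beta[setdiff(names(beta), c("(Intercept)", drop_terms))]
  missing <- setdiff(names(beta), names(rows))
  if (length(missing))
    stop("rows lack covariate column(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(rows[, names(beta), drop = FALSE])
  exp(as.vector(X %*% beta))
}

#' Quantile-bin calibration of held-out predictions
#'
#' Johnson-style calibration: bin boundaries are the deciles of `w` over the
#' held-out availability sample; the expected number of used locations in
#' bin b is `n_used * sum(w available in b) / sum(w all available)`; observed
#' is the count of held-out used locations whose `w` falls in b. Reports the
#' slope and R-squared of the observed-on-expected linear regression and the
#' Spearman correlation between observed counts and bin rank. Tied deciles
#' that collapse a bin are merged with a warning.
#'
#' @param w_available,w_used RSF values at held-out available / used points.
#' @param n_bins number of quantile bins.
#' @return An `rsf_calibration` list: `bins` (`data.frame` with boundaries,
#'   `observed`, `expected`), `slope`, `intercept`, `r_squared`, `spearman`,
#'   plus a no-intercept slope `slope_through_origin`.
#' @export
calibration_bins <- function(w_available, w_used, n_bins = 10) {
  if (!length(w_available) || !length(w_used))
    stop("both the available and used sets must be nonempty")
  qs <- stats::quantile(w_available, probs = seq(0, 1, length.out = n_bins + 1))
  brk <- unique(unname(qs))
  if (length(brk) < n_bins + 1)
    warning("tied quantiles collapsed ", n_bins + 1 - length(brk),
            " bin boundary(ies); bins merged")
  if (length(brk) < 2) brk <- c(brk, brk)  # constant w: a single bin
  brk[1] <- -Inf; brk[length(brk)] <- Inf
  ba <- cut(w_available, brk, labels = FALSE)
  bu <- cut(w_used, brk, labels = FALSE)
  nb <- length(brk) - 1
  n_used <- length(w_used)
  wsum <- vapply(seq_len(nb), function(b) sum(w_available[ba == b]), numeric(1))
  expected <- n_used * wsum / sum(w_available)
  observed <- tabulate(bu, nbins = nb)
  if (nb >= 2) {
    fit <- stats::lm(observed ~ expected)
    fit0 <- stats::lm(observed ~ expected - 1)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    slope0 <- unname(stats::coef(fit0)[1])
    r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
    rho <- suppressWarnings(stats::cor(observed, seq_len(nb),
                                       method = "spearman"))
  } else {
    slope <- intercept <- slope0 <- r2 <- rho <- NA_real_
  }
  structure(list(
    bins = data.frame(bin = seq_len(nb), lower = brk[-length(brk)],
                      upper = brk[-1], observed = observed, expected = expected),
    slope = slope, intercept = intercept, slope_through_origin = slope0,
    r_squared = r2, spearman = rho,
    n_used = n_used
  ), class = "rsf_calibration")
}

#' @export
print.rsf_calibration <- function(x, ...) {
  cat(sprintf(
    "<rsf_calibration> %d bins, %d used: slope %.3f, R^2 %.3f, Spearman %.3f\n",
    nrow(x$bins), x$n_used, x$slope, x$r_squared, x$spearman))
  invisible(x)
}

#' Calibration plot
#' @param x an `rsf_calibration`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rsf_calibration <- function(x, ...) {
  graphics::plot(x$bins$expected, x$bins$observed,
                 xlab = "Expected used locations", ylab = "Observed used locations",
                 pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(x$intercept, x$slope, col = "steelblue")
}

#' Used-habitat calibration (UHC) envelope for one covariate
#'
#' For each of M posterior draws, held-out availability points are resampled
#' (with replacement, size = number of held-out used points) with probability
#' proportional to that draw's RSF values; the covariate's kernel density
#' over the resample contributes one replicate curve. The envelope is the
#' pointwise 2.5-97.5 percentile band across replicates; a well-specified
#' model's observed used-density curve lies almost entirely inside it, and a
#' model missing a truly selected covariate fails on that covariate.
#'
#' Densities use a Gaussian kernel with Silverman's bandwidth (fixed from the
#' availability values) on a 512-point grid spanning the pooled 0.5-99.5
#' percentiles.
#'
#' @param fit an `rsf_posterior` from the training fit.
#' @param test_design held-out rows of the standardized design.
#' @param covariate covariate column name.
#' @param M number of posterior replicates (>= 2).
#' @param seed integer seed for the resampling.
#' @param drop_terms terms excluded from prediction (release decay etc.).
#' @return An `rsf_uhc` list: `grid`, `observed`, `availability`, `lower`,
#'   `upper`, `coverage` (fraction of the observed curve inside the band).
#' @export
uhc_envelope <- function(fit, test_design, covariate, M = 1000, seed = 1,
                         drop_terms = character(0)) {
  if (M < 2) stop("need at least 2 posterior replicates for an envelope")
  set.seed(seed)
  avail <- test_design[test_design$used == 0, , drop = FALSE]
  used <- test_design[test_design$used == 1, , drop = FALSE]
  n_used <- nrow(used)

  pooled <- c(avail[[covariate]], used[[covariate]])
  rng <- stats::quantile(pooled, c(0.005, 0.995))
  grid <- seq(rng[1], rng[2], length.out = 512)
  bw <- stats::bw.nrd0(avail[[covariate]])
  dens <- function(v) stats::density(v, bw = bw, from = rng[1], to = rng[2],
                                     n = 512)$y

  draws <- as.matrix(fit)[, fit$coef_names, drop = FALSE]
  keep <- setdiff(colnames(draws), drop_terms)
  Xa <- as.matrix(avail[, keep, drop = FALSE])
  pick <- sample(nrow(draws), M, replace = M > nrow(draws))
  reps <- matrix(NA_real_, M, 512)
  for (i in seq_len(M)) {
    w <- exp(as.vector(Xa %*% draws[pick[i], keep]))
    idx <- sample.int(nrow(avail), n_used, replace = TRUE, prob = w)
    reps[i, ] <- dens(avail[[covariate]][idx])
  }
  lower <- apply(reps, 2, stats::quantile, 0.025)
  upper <- apply(reps, 2, stats::quantile, 0.975)
  observed <- dens(used[[covariate]])
  structure(list(
    covariate = covariate, grid = grid, observed = observed,
    availability = dens(avail[[covariate]]),
    lower = lower, upper = upper,
    coverage = mean(observed >= lower & observed <= upper)
  ), class = "rsf_uhc")
}

#' @export
print.rsf_uhc <- function(x, ...) {
  cat(sprintf("<rsf_uhc> %s: %.1f%% of the observed use density inside the envelope\n",
              x$covariate, 100 * x$coverage))
  invisible(x)
}

#' UHC plot
#' @param x an `rsf_uhc`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rsf_uhc <- function(x, ...) {
  graphics::plot(x$grid, x$observed, type = "n",
                 ylim = range(0, x$upper, x$observed),
                 xlab = x$covariate, ylab = "Density", ...)
  graphics::polygon(c(x$grid, rev(x$grid)), c(x$lower, rev(x$upper)),
                    col = "grey85", border = NA)
  graphics::lines(x$grid, x$availability, lty = 2, col = "steelblue")
  graphics::lines(x$grid, x$observed, col = "darkgreen")
}

#' Held-out calibration of a fitted RSF
#'
#' Convenience wrapper: predicts `w` on the test partition (intercept
#' dropped, all habitat terms — including the release-site decay — kept,
#' since validation asks whether the fitted ŵ predicts where locations
#' fall; the release term is dropped only for spatial habitat maps) and
#' runs [calibration_bins()].
#'
#' @param fit an `rsf_posterior`.
#' @param design the standardized, split design the fit came from (or a
#'   fixed-scale version of it).
#' @param drop_terms terms excluded from prediction.
#' @param n_bins number of calibration bins.
#' @return An `rsf_calibration`.
#' @export
validate_holdout <- function(fit, design, drop_terms = character(0), n_bins = 10) {
  test <- design[design$split == "test", , drop = FALSE]
  w <- predict_w(fit, test, drop_terms = drop_terms)
  calibration_bins(w[test$used == 0], w[test$used == 1], n_bins = n_bins)
}

#' Add a squared covariate column
#'
#' Appends the square of a (standardized) covariate, itself standardized on
#' the training rows so its coefficient is comparable, named `cov^2`.
#'
#' @param design a standardized `rsf_design` with fixed scales.
#' @param covariate column to square.
#' @return The extended design.
#' @export
add_quadratic <- function(design, covariate) {
  nm <- paste0(covariate, "^2")
  sq <- design[[covariate]]^2
  ref <- if ("split" %in% names(design)) which(design$split == "train")
         else seq_len(nrow(design))
  mu <- mean(sq[ref]); sdv <- stats::sd(sq[ref])
  if (sdv == 0) stop("squared column has zero variance")
  design[[nm]] <- (sq - mu) / sdv
  attr(design, "covariates") <- c(attr(design, "covariates"), nm)
  sc <- attr(design, "scaling")
  if (!is.null(sc))
    attr(design, "scaling") <- rbind(sc, data.frame(column = nm, mean = mu, sd = sdv))
  attr(design, "quadratic") <- c(attr(design, "quadratic"), covariate)
  design
}

#' Escalate quadratic terms until calibration passes
#'
#' Starting from a fitted base model, while the held-out calibration misses
#' any threshold (Spearman > .75, R-squared > .75, slope within
#' \[0.8, 1.2\]) and unsquared predictors remain, the square of the
#' not-yet-squared predictor with the largest absolute posterior mean is
#' added and the model refitted and revalidated. Exhausting all predictors
#' without passing is a reported outcome, not an error.
#'
#' @param design a standardized, split, fixed-scale `rsf_design`.
#' @param config an [rsf_model_config()].
#' @param fit optional pre-fitted base model (refit if `NULL`).
#' @param thresholds list with `spearman`, `r_squared`, `slope_range`.
#' @param drop_terms prediction drop terms.
#' @return List: `fit`, `design`, `calibration`, `quadratic_terms` (added,
#'   in order), `passed`.
#' @export
escalate_quadratic <- function(design, config = rsf_model_config(), fit = NULL,
                               thresholds = list(spearman = 0.75,
                                                 r_squared = 0.75,
                                                 slope_range = c(0.8, 1.2)),
                               drop_terms = character(0)) {
  if (is.null(fit)) fit <- fit_rsf(design, config, sample_scales = FALSE)
  cal <- validate_holdout(fit, design, drop_terms = drop_terms)
  passes <- function(cal) {
    cal$spearman > thresholds$spearman &&
      cal$r_squared > thresholds$r_squared &&
      cal$slope >= thresholds$slope_range[1] &&
      cal$slope <= thresholds$slope_range[2]
  }
  added <- character(0)
  while (!passes(cal)) {
    done <- attr(design, "quadratic")
    cand <- setdiff(setdiff(fit$coef_names, drop_terms),
                    c(done, grep("\\^2$", fit$coef_names, value = TRUE)))
    if (!length(cand)) break
    means <- colMeans(as.matrix(fit)[, cand, drop = FALSE])
    pick <- cand[which.max(abs(means))]
    design <- add_quadratic(design, pick)
    added <- c(added, pick)
    fit <- fit_rsf(design, config, sample_scales = FALSE)
    cal <- validate_holdout(fit, design, drop_terms = drop_terms)
  }
  list(fit = fit, design = design, calibration = cal,
       quadratic_terms = added, passed = passes(cal))
}
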