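#' MCMC configuration for the Bayesian RSF
#'
#' Defaults follow the study protocol: three chains of 30,000 iterations
#' after a 15,000-iteration burn-in, thinned to every 5th sample, Laplace
#' (Lasso) shrinkage priors on all habitat coefficients with a
#' Gamma(0.01, 0.01) hyperprior on the shrinkage parameter lambda, a diffuse
#' Normal(0, 10^2) prior on the intercept (discarded for the RSF anyway) and
#' a Uniform(0, 10) prior on the random-intercept SD. Random-walk Metropolis
#' step sizes adapt towards 0.44 acceptance during burn-in only.
#'
#' @param chains,iterations,burn_in,thin chain layout; retained draws per
#'   chain are `(iterations - burn_in) / thin`.
#' @param a,b shape and rate of the Gamma hyperprior on lambda.
#' @param random_intercept fit per-individual random intercepts.
#' @param re_upper upper bound of the Uniform prior on the random-effect SD.
#' @param beta0_sd SD of the Normal prior on the intercept.
#' @param seed base seed; chain c uses `seed + c - 1`.
#' @return An `rsf_model_config` list.
#' @export
rsf_model_config <- function(chains = 3, iterations = 30000, burn_in = 15000,
                             thin = 5, a = 0.01, b = 0.01,
                             random_intercept = FALSE, re_upper = 10,
                             beta0_sd = 10, seed = 1) {
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  if (thin < 1) stop("thin must be >= 1")
  if (a <= 0 || b <= 0) stop("hyperprior shape and rate must be positive")
  structure(list(chains = as.integer(chains), iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 a = a, b = b, random_intercept = isTRUE(random_intercept),
                 re_upper = re_upper, beta0_sd = beta0_sd,
                 seed = as.integer(seed)),
            class = "rsf_model_config")
}

#' Fit the use-availability Bayesian RSF by MCMC
#'
#' Bernoulli logistic model on used (1) vs available (0) rows with Laplace
#' shrinkage priors on all covariate coefficients, the exact conjugate Gamma
#' Gibbs update for the shrinkage parameter lambda, optional per-individual
#' random intercepts, and — when the design carries multi-scale candidate
#' columns — a latent categorical indicator per multi-scale variable that
#' selects, at every iteration, which candidate radius's column carries that
#' variable's (shared) coefficient. Runs are reproducible: chain `c` is
#' seeded with `config$seed + c - 1`.
#'
#' @param design an `rsf_design`, standardized ([standardize_design()]).
#' @param config an [rsf_model_config()].
#' @param use_split which rows to fit on when the design is split
#'   (`"train"`), or `NULL` for all rows.
#' @param sample_scales run the latent-indicator scale-selection step
#'   (ignored when the design has no multi-scale candidates).
#' @return An `rsf_posterior` object; its `convergence` element holds the
#'   Gelman-Rubin report and `converged` the overall pass flag (a failed
#'   check warns, never silently drops).
#' @export
fit_rsf <- function(design, config = rsf_model_config(), use_split = "train",
                    sample_scales = TRUE) {
  rows <- if (!is.null(use_split) && "split" %in% names(design))
    which(design$split == use_split) else seq_len(nrow(design))
  d <- design[rows, , drop = FALSE]

  singles <- single_scale_covariates(design)
  ms_map <- attr(design, "ms_map")
  ms_map <- ms_map[lengths(ms_map) > 0]
  all_cols <- c(singles, unlist(ms_map, use.names = FALSE))
  X <- as.matrix(d[, all_cols, drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite covariate values in the design")
  y <- as.integer(d$used)

  if (config$random_intercept) {
    fac <- factor(d$individual_id)
    ind <- as.integer(fac)
    ind_levels <- levels(fac)
  } else {
    ind <- rep(0L, nrow(d))
    ind_levels <- character(0)
  }

  single_idx <- match(singles, all_cols)
  ms_idx <- lapply(ms_map, function(cols) match(cols, all_cols))
  scale_init <- vapply(ms_idx, function(ix) 1L, integer(1))
  do_scales <- sample_scales && length(ms_idx) > 0

  coef_names <- c(singles, names(ms_map))
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + ch - 1L)
    res <- rsf_mcmc_cpp(X, y, ind,
                        as.integer(single_idx), ms_idx,
                        config$iterations, config$burn_in, config$thin,
                        config$a, config$b,
                        config$random_intercept, config$re_upper,
                        config$beta0_sd,
                        do_scales, as.integer(scale_init), 1.0)
    draws <- cbind(res$beta0, res$beta, res$lambda)
    cn <- c("(Intercept)", coef_names, "lambda")
    if (config$random_intercept) {
      draws <- cbind(draws, res$sigma_gamma)
      cn <- c(cn, "sigma_gamma")
    }
    colnames(draws) <- cn
    sc <- res$scale
    if (length(ms_map)) colnames(sc) <- names(ms_map)
    gamma <- if (config$random_intercept) {
      g <- res$gamma; colnames(g) <- ind_levels; g
    } else NULL
    chains[[ch]] <- list(draws = draws, scale = sc, gamma = gamma)
  }

  fit <- structure(list(
    chains = chains,
    coef_names = coef_names,
    ms_map = ms_map,
    config = config,
    scaling = attr(design, "scaling"),
    alphas = attr(design, "alphas"),
    n_rows = nrow(d)
  ), class = "rsf_posterior")

  if (config$chains < 2) {
    fit$convergence <- NULL
    fit$converged <- NA
    return(fit)
  }
  fit$convergence <- gelman_rubin(lapply(chains, `[[`, "draws"))
  fit$converged <- isTRUE(fit$convergence$pass)
  if (!fit$converged)
    warning("Gelman-Rubin check failed: max rhat = ",
            signif(max(fit$convergence$table$rhat, na.rm = TRUE), 4))
  fit
}

#' @export
print.rsf_posterior <- function(x, ...) {
  cat(sprintf("<rsf_posterior> %d chains x %d draws, %d coefficients\n",
              length(x$chains), nrow(x$chains[[1]]$draws), length(x$coef_names)))
  cat(sprintf("  converged (all rhat < 1.05): %s\n", x$converged))
  print(posterior_summary(x)[x$coef_names, ])
  invisible(x)
}

#' Pooled posterior draws
#'
#' @param x an `rsf_posterior`.
#' @param ... unused.
#' @return Matrix of retained draws (all chains stacked) with named columns.
#' @export
as.matrix.rsf_posterior <- function(x, ...) {
  do.call(rbind, lapply(x$chains, `[[`, "draws"))
}

#' Joint log-posterior of the RSF model
#'
#' Direct evaluation of the (unnormalized) log-posterior at a given state:
#' Bernoulli log-likelihood with `p = plogis(beta0 + sum beta_k x_k + gamma_j)`
#' (multi-scale covariates evaluated at the column named in `state$scales`),
#' plus the Laplace log-prior `K log(lambda/2) - lambda sum |beta_k|`, the
#' Gamma(a, b) log-density of lambda, Normal(0, sigma_gamma) terms for the
#' random intercepts with their Uniform(0, U) SD prior, and the Normal
#' intercept prior. Used as the reference the sampler is tested against.
#'
#' @param state list with `beta0`, named `beta` (one entry per single-scale
#'   covariate and per multi-scale variable), `lambda`, optionally `gamma`
#'   (named by individual) and `sigma_gamma`, and `scales` (named character:
#'   multi-scale variable -> selected column name).
#' @param design an `rsf_design` (all rows are used).
#' @param config an [rsf_model_config()].
#' @return A finite scalar.
#' @export
log_posterior <- function(state, design, config = rsf_model_config()) {
  singles <- single_scale_covariates(design)
  ms_map <- attr(design, "ms_map")
  ms_map <- ms_map[lengths(ms_map) > 0]
  cols <- c(stats::setNames(singles, singles),
            if (length(ms_map)) unlist(state$scales[names(ms_map)]))
  X <- as.matrix(design[, unname(cols), drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite covariates")
  beta <- state$beta[names(cols)]
  eta <- state$beta0 + as.vector(X %*% beta)
  if (!is.null(state$gamma)) {
    g <- state$gamma[as.character(design$individual_id)]
    eta <- eta + unname(g)
  }
  y <- design$used
  ll <- sum(y * eta - log1p(exp(eta)))
  K <- length(beta)
  lp <- ll +
    K * log(state$lambda / 2) - state$lambda * sum(abs(beta)) +
    stats::dgamma(state$lambda, shape = config$a, rate = config$b, log = TRUE) +
    stats::dnorm(state$beta0, 0, config$beta0_sd, log = TRUE)
  if (!is.null(state$gamma)) {
    lp <- lp + sum(stats::dnorm(state$gamma, 0, state$sigma_gamma, log = TRUE)) +
      stats::dunif(state$sigma_gamma, 0, config$re_upper, log = TRUE)
  }
  if (!is.finite(lp)) stop("log-posterior is not finite at this state")
  lp
}

#' Conjugate Gibbs draw of the shrinkage parameter
#'
#' Under K independent Laplace(0, lambda) coefficient priors and a
#' Gamma(a, b) hyperprior, the full conditional of lambda is exactly
#' Gamma(shape = a + K, rate = b + sum |beta_k|).
#'
#' @param beta current coefficient vector (the K Lasso-shrunk coefficients).
#' @param a,b hyperprior shape and rate.
#' @param n number of draws.
#' @return `n` draws from the full conditional.
#' @export
update_lambda_gibbs <- function(beta, a = 0.01, b = 0.01, n = 1) {
  if (a <= 0 || b <= 0) stop("a and b must be positive")
  stats::rgamma(n, shape = a + length(beta), rate = b + sum(abs(beta)))
}

#' Gelman-Rubin convergence diagnostic
#'
#' For each parameter: W is the mean within-chain variance, B/n the variance
#' of the chain means, `Vhat = ((n-1)/n) W + B/n`, and
#' `rhat = sqrt(Vhat / W)`. Parameters with zero within-chain variance are
#' flagged as undefined. The report passes when every defined rhat is below
#' 1.05 and none is undefined with disagreeing chains.
#'
#' @param chains list (length >= 2) of draw matrices with identical named
#'   columns, or list of numeric vectors for a single parameter.
#' @return List: `table` (`data.frame` with `parameter`, `rhat`, `flag`) and
#'   `pass`.
#' @export
gelman_rubin <- function(chains) {
  if (length(chains) < 2) stop("need at least 2 chains")
  if (!is.matrix(chains[[1]]))
    chains <- lapply(chains, function(v) matrix(v, ncol = 1,
                                                dimnames = list(NULL, "par")))
  n <- nrow(chains[[1]])
  if (n < 2) stop("need at least 2 retained draws per chain")
  params <- colnames(chains[[1]])
  rhat <- flag <- stats::setNames(numeric(length(params)), params)
  for (p in params) {
    draws <- vapply(chains, function(m) m[, p], numeric(n))
    W <- mean(apply(draws, 2, stats::var))
    B_n <- stats::var(colMeans(draws))
    if (W == 0) {
      rhat[p] <- NA_real_
      # identical constant chains are converged; differing constants are not
      flag[p] <- as.numeric(B_n > 0)
    } else {
      rhat[p] <- sqrt(((n - 1) / n * W + B_n) / W)
      flag[p] <- 0
    }
  }
  tab <- data.frame(parameter = params, rhat = unname(rhat),
                    flag = unname(flag) == 1, row.names = NULL)
  pass <- all(!tab$flag) && all(is.na(tab$rhat) | tab$rhat < 1.05)
  list(table = tab, pass = pass)
}

#' Posterior probabilities of each candidate scale
#'
#' Frequencies of the latent scale indicator across all retained draws; the
#' probabilities for each multi-scale variable sum to 1, and the modal radius
#' is the candidate selected for the second-stage refit.
#'
#' @param fit an `rsf_posterior` from a scale-sampling run.
#' @return `data.frame` with `variable`, `column`, `radius`, `prob`, `modal`.
#' @export
scale_probabilities <- function(fit) {
  if (!length(fit$ms_map)) stop("fit has no multi-scale variables")
  out <- list()
  for (v in names(fit$ms_map)) {
    cols <- fit$ms_map[[v]]
    sel <- unlist(lapply(fit$chains, function(ch) ch$scale[, v]))
    p <- tabulate(sel, nbins = length(cols)) / length(sel)
    radius <- as.numeric(sub(".*@", "", cols))
    out[[v]] <- data.frame(variable = v, column = cols, radius = radius,
                           prob = p, modal = seq_along(cols) == which.max(p))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Fix multi-scale variables at chosen radii
#'
#' Rewrites a design so each multi-scale variable keeps only the selected
#' candidate column, renamed to the bare variable name; used between the two
#' modeling stages and for contrast/escalation refits.
#'
#' @param design an `rsf_design`.
#' @param scales named character (variable -> selected column name, e.g.
#'   `c(shrub = "shrub@887")`).
#' @return The single-scale design.
#' @export
fix_scales <- function(design, scales) {
  ms_map <- attr(design, "ms_map")
  covs <- attr(design, "covariates")
  for (v in names(scales)) {
    keep <- scales[[v]]
    drop <- setdiff(ms_map[[v]], keep)
    design[drop] <- NULL
    names(design)[names(design) == keep] <- v
    covs <- c(setdiff(covs, ms_map[[v]]), v)
    sc <- attr(design, "scaling")
    if (!is.null(sc)) {
      sc <- sc[!sc$column %in% drop, ]
      sc$column[sc$column == keep] <- v
      attr(design, "scaling") <- sc
    }
  }
  attr(design, "covariates") <- covs
  attr(design, "ms_map") <- list()
  attr(design, "selected_scales") <- scales
  design
}

#' Two-stage fit: scale selection, then refit at the modal scales
#'
#' Stage 1 fits the full model with latent-indicator scale selection and
#' extracts the posterior scale probabilities; stage 2 refits with each
#' multi-scale variable fixed at its modal radius. Non-convergence in either
#' stage propagates through the `converged` flag.
#'
#' @param design a standardized, split `rsf_design`.
#' @param config an [rsf_model_config()].
#' @return List: `scale_posterior`, `modal_scales` (named columns),
#'   `stage1`, `fit` (the stage-2 posterior), `design` (the fixed-scale
#'   design), `converged`.
#' @export
two_stage_fit <- function(design, config = rsf_model_config()) {
  stage1 <- fit_rsf(design, config, sample_scales = TRUE)
  sp <- scale_probabilities(stage1)
  modal <- stats::setNames(sp$column[sp$modal], sp$variable[sp$modal])
  d2 <- fix_scales(design, modal)
  fit <- fit_rsf(d2, config, sample_scales = FALSE)
  list(scale_posterior = sp, modal_scales = modal, stage1 = stage1,
       fit = fit, design = d2,
       converged = stage1$converged && fit$converged)
}

#' Influential covariates by posterior sign probability
#'
#' A covariate is influential when the posterior probability of its
#' coefficient being positive is at least `level`, or at most `1 - level`
#' (boundary inclusive).
#'
#' @param fit an `rsf_posterior`.
#' @param level posterior-probability threshold (default 0.85).
#' @return `data.frame` with `parameter`, `prob_positive`, `influential`.
#' @export
influence_flags <- function(fit, level = 0.85) {
  m <- as.matrix(fit)[, fit$coef_names, drop = FALSE]
  p <- colMeans(m > 0)
  data.frame(parameter = colnames(m), prob_positive = unname(p),
             influential = unname(p >= level | p <= 1 - level),
             row.names = NULL)
}

#' Posterior contrast between two coefficients
#'
#' Fraction of retained draws in which the first coefficient exceeds the
#' second (draws paired by iteration); values above 0.95 or below 0.05
#' constitute strong evidence of a group difference.
#'
#' @param fit an `rsf_posterior`, or `NULL` when raw draw vectors are given.
#' @param par_a,par_b parameter names in `fit`, or numeric draw vectors.
#' @return The contrast probability.
#' @export
group_contrast <- function(fit, par_a, par_b) {
  if (is.null(fit)) {
    a <- par_a; b <- par_b
  } else {
    m <- as.matrix(fit)
    a <- m[, par_a]; b <- m[, par_b]
  }
  if (length(a) != length(b)) stop("draw vectors are not paired (lengths differ)")
  mean(a > b)
}

#' Posterior summary table
#'
#' Mean, median and equal-tailed 68% and 95% credible intervals per
#' parameter.
#'
#' @param fit an `rsf_posterior` or a draws matrix.
#' @return `data.frame` with one row per parameter.
#' @export
posterior_summary <- function(fit) {
  m <- if (inherits(fit, "rsf_posterior")) as.matrix(fit) else as.matrix(fit)
  q <- t(apply(m, 2, stats::quantile, probs = c(0.025, 0.16, 0.5, 0.84, 0.975)))
  data.frame(mean = colMeans(m), median = q[, 3],
             lo68 = q[, 2], hi68 = q[, 4], lo95 = q[, 1], hi95 = q[, 5])
}

#' Split covariates into group-specific columns
#'
#' For each named covariate, replaces the column with one column per group
#' (`x * 1[group == g]`, zero elsewhere), enabling group-specific
#' coefficients (e.g. resident vs translocated) in an otherwise shared
#' model; the new columns are named `covariate:group`.
#'
#' @param design an `rsf_design` with a `group` column (single-scale; run
#'   [fix_scales()] first for multi-scale variables).
#' @param covariates covariate names to split.
#' @return The expanded design.
#' @export
expand_group_columns <- function(design, covariates) {
  groups <- sort(unique(stats::na.omit(design$group)))
  if (length(groups) < 2) stop("need at least two groups")
  covs <- attr(design, "covariates")
  sc <- attr(design, "scaling")
  for (cv in covariates) {
    for (g in groups) {
      nm <- paste0(cv, ":", g)
      design[[nm]] <- design[[cv]] * as.numeric(design$group == g)
      covs <- c(covs, nm)
      if (!is.null(sc)) {
        row <- sc[sc$column == cv, ]
        row$column <- nm
        sc <- rbind(sc, row)
      }
    }
    design[[cv]] <- NULL
    covs <- setdiff(covs, cv)
    if (!is.null(sc)) sc <- sc[sc$column != cv, ]
  }
  attr(design, "covariates") <- covs
  attr(design, "scaling") <- sc
  design
}
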