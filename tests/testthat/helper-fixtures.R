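# Shared fixtures: small landscapes and hand-built designs used across tests.

tiny_landscape <- function(seed = 42, nx = 50, ny = 50, smooth_range = 150) {
  generate_landscape(landscape_config(nx = nx, ny = ny,
                                      smooth_range = smooth_range),
                     seed = seed)
}

# Build an rsf_design directly from covariate data frames (bypasses the
# raster pipeline for model-level tests).
make_design <- function(used_x, avail_x, ms_map = list(),
                        individual = NULL, split = NULL,
                        alphas = numeric(0)) {
  used_x <- as.data.frame(used_x, check.names = FALSE)
  avail_x <- as.data.frame(avail_x, check.names = FALSE)
  n1 <- nrow(used_x); n0 <- nrow(avail_x)
  d <- rbind(used_x, avail_x)
  d$used <- c(rep(1L, n1), rep(0L, n0))
  d$individual_id <- if (is.null(individual)) rep("a", n1 + n0) else individual
  d$unit <- d$individual_id
  d$group <- NA_character_
  if (!is.null(split)) d$split <- split
  structure(d, class = c("rsf_design", "data.frame"),
            covariates = names(used_x), ms_map = ms_map, alphas = alphas)
}

# Simulated logistic use-availability data with known coefficients.
sim_logistic_design <- function(n = 600, beta = c(x1 = 1, x2 = -0.5),
                                beta0 = -1, seed = 1, individual = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(beta)), n, length(beta),
              dimnames = list(NULL, names(beta)))
  eta <- beta0 + X %*% beta
  y <- rbinom(n, 1, plogis(eta))
  d <- as.data.frame(X)
  d$used <- y
  d$individual_id <- if (is.null(individual)) rep("a", n) else individual
  d$unit <- d$individual_id
  d$group <- NA_character_
  structure(d, class = c("rsf_design", "data.frame"),
            covariates = names(beta), ms_map = list(), alphas = numeric(0))
}

quick_config <- function(...) {
  args <- utils::modifyList(
    list(chains = 2, iterations = 4000, burn_in = 2000, thin = 2, seed = 7),
    list(...))
  do.call(rsf_model_config, args)
}
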