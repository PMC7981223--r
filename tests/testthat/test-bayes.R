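test_that("log posterior matches an independent term-by-term evaluation", {
  d <- make_design(data.frame(a = c(0.5, -1), b = c(1, 0)),
                   data.frame(a = 0.2, b = -0.3))
  cfg <- rsf_model_config()
  state <- list(beta0 = 0.3, beta = c(a = 0.8, b = -0.4), lambda = 1.7)
  got <- log_posterior(state, d, cfg)

  # brute-force oracle: everything summed explicitly, row by row
  oracle <- 0
  for (i in 1:3) {
    eta <- state$beta0 + state$beta[["a"]] * d$a[i] + state$beta[["b"]] * d$b[i]
    p <- 1 / (1 + exp(-eta))
    oracle <- oracle + d$used[i] * log(p) + (1 - d$used[i]) * log(1 - p)
  }
  for (bk in state$beta)
    oracle <- oracle + log(state$lambda / 2) - state$lambda * abs(bk)
  oracle <- oracle + dgamma(state$lambda, cfg$a, rate = cfg$b, log = TRUE) +
    dnorm(state$beta0, 0, cfg$beta0_sd, log = TRUE)
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("log posterior: null coefficients give -N log 2 likelihood", {
  d <- make_design(data.frame(a = c(1, 2)), data.frame(a = c(-1, 0)))
  cfg <- rsf_model_config()
  state0 <- list(beta0 = 0, beta = c(a = 0), lambda = 1)
  lp <- log_posterior(state0, d, cfg)
  prior <- log(1 / 2) + dgamma(1, cfg$a, rate = cfg$b, log = TRUE) +
    dnorm(0, 0, cfg$beta0_sd, log = TRUE)
  expect_equal(lp - prior, -4 * log(2), tolerance = 1e-12)
})

test_that("doubling lambda changes the Laplace part by K log 2 - lambda sum|beta|", {
  d <- make_design(data.frame(a = c(0.5, -1), b = c(1, 0)),
                   data.frame(a = 0.2, b = -0.3))
  cfg <- rsf_model_config()
  beta <- c(a = 0.8, b = -0.4)
  lam <- 0.9
  lp1 <- log_posterior(list(beta0 = 0, beta = beta, lambda = lam), d, cfg)
  lp2 <- log_posterior(list(beta0 = 0, beta = beta, lambda = 2 * lam), d, cfg)
  hyper <- dgamma(2 * lam, cfg$a, rate = cfg$b, log = TRUE) -
    dgamma(lam, cfg$a, rate = cfg$b, log = TRUE)
  expect_equal(lp2 - lp1 - hyper, 2 * log(2) - lam * sum(abs(beta)),
               tolerance = 1e-12)
})

test_that("lambda full conditional is Gamma(a + K, b + sum|beta|)", {
  beta <- c(1.2, -0.8)   # K = 2, sum|beta| = 2
  a <- 0.01; b <- 0.01
  # density-ratio identity against the joint log posterior
  d <- make_design(data.frame(a = c(0.5, -1), b = c(1, 0)),
                   data.frame(a = 0.2, b = -0.3))
  cfg <- rsf_model_config()
  st <- function(l) list(beta0 = 0.1, beta = c(a = beta[1], b = beta[2]),
                         lambda = l)
  for (pair in list(c(0.5, 1.5), c(2, 0.2), c(3.3, 1.1))) {
    lhs <- log_posterior(st(pair[1]), d, cfg) - log_posterior(st(pair[2]), d, cfg)
    rhs <- dgamma(pair[1], a + 2, rate = b + 2, log = TRUE) -
      dgamma(pair[2], a + 2, rate = b + 2, log = TRUE)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  # Monte-Carlo mean within 1% of (a + K) / (b + sum|beta|)
  set.seed(11)
  draws <- update_lambda_gibbs(beta, a, b, n = 1e5)
  expect_equal(mean(draws), (a + 2) / (b + 2), tolerance = 0.01)
  expect_true(all(draws > 0))
})

test_that("Gelman-Rubin: hand value, long-run behaviour, degeneracies", {
  out <- gelman_rubin(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(out$table$rhat, sqrt(3 / 4), tolerance = 1e-12)
  expect_true(out$pass)  # rhat < 1.05

  set.seed(12)
  long <- gelman_rubin(list(rnorm(5000), rnorm(5000)))
  expect_gt(long$table$rhat, 0.99)
  expect_lt(long$table$rhat, 1.02)

  deg <- gelman_rubin(list(rep(0, 4), rep(5, 4)))
  expect_true(is.na(deg$table$rhat))
  expect_true(deg$table$flag)
  expect_false(deg$pass)
  expect_error(gelman_rubin(list(1:4)), "2 chains")
})

test_that("sampler recovers known coefficients and is reproducible", {
  d <- sim_logistic_design(600, beta = c(x1 = 1, x2 = -0.5), seed = 21)
  cfg <- quick_config()
  fit <- fit_rsf(d, cfg, use_split = NULL)
  m <- colMeans(as.matrix(fit))
  expect_lt(abs(m[["x1"]] - 1), 0.15)
  expect_lt(abs(m[["x2"]] + 0.5), 0.15)
  expect_true(all(as.matrix(fit)[, "lambda"] > 0))
  # retained-draw bookkeeping
  expect_equal(nrow(fit$chains[[1]]$draws),
               (cfg$iterations - cfg$burn_in) / cfg$thin)

  fit2 <- fit_rsf(d, cfg, use_split = NULL)
  expect_identical(as.matrix(fit), as.matrix(fit2))
})

test_that("Lasso prior shrinks a pure-noise covariate", {
  set.seed(22)
  d <- sim_logistic_design(600, beta = c(x1 = 1, x2 = -0.5), seed = 22)
  d$noise <- rnorm(nrow(d))
  attr(d, "covariates") <- c(attr(d, "covariates"), "noise")
  fit <- fit_rsf(d, quick_config(), use_split = NULL)
  m <- colMeans(as.matrix(fit))
  expect_lt(abs(m[["noise"]]), abs(m[["x1"]]) / 3)
})

test_that("posterior matches a fine-grid quadrature of the exact posterior", {
  d <- sim_logistic_design(300, beta = c(x1 = 0.8, x2 = -0.6), seed = 23)
  cfg <- rsf_model_config(chains = 2, iterations = 12000, burn_in = 4000,
                          thin = 2, seed = 31)
  fit <- fit_rsf(d, cfg, use_split = NULL)
  m <- as.matrix(fit)

  # independent oracle: grid quadrature with lambda integrated out
  # analytically (Laplace priors with Gamma(a,b) hyperprior give
  # p(beta) = Gamma(a+K) b^a / (Gamma(a) 2^K (b + sum|beta|)^(a+K)))
  X <- as.matrix(d[, c("x1", "x2")])
  y <- d$used
  mle <- glm(y ~ X, family = binomial)
  ctr <- coef(mle); se <- sqrt(diag(vcov(mle)))
  gr <- lapply(1:3, function(i) seq(ctr[i] - 5 * se[i], ctr[i] + 5 * se[i],
                                    length.out = 41))
  g12 <- as.matrix(expand.grid(b1 = gr[[2]], b2 = gr[[3]]))
  eta12 <- X %*% t(g12)                       # n x 1681
  a <- cfg$a; b <- cfg$b; K <- 2
  lprior12 <- lgamma(a + K) + a * log(b) - lgamma(a) - K * log(2) -
    (a + K) * log(b + abs(g12[, 1]) + abs(g12[, 2]))
  lp <- matrix(NA_real_, 41, nrow(g12))
  for (i in 1:41) {
    eta <- eta12 + gr[[1]][i]
    lp[i, ] <- colSums(y * eta - log1p(exp(eta))) + lprior12 +
      dnorm(gr[[1]][i], 0, cfg$beta0_sd, log = TRUE)
  }
  w <- exp(lp - max(lp)); w <- w / sum(w)
  mean_b1 <- sum(w * matrix(g12[, 1], 41, nrow(g12), byrow = TRUE))
  mean_b2 <- sum(w * matrix(g12[, 2], 41, nrow(g12), byrow = TRUE))
  sd_b1 <- sqrt(sum(w * (matrix(g12[, 1], 41, nrow(g12), byrow = TRUE) - mean_b1)^2))
  sd_b2 <- sqrt(sum(w * (matrix(g12[, 2], 41, nrow(g12), byrow = TRUE) - mean_b2)^2))

  expect_lt(abs(mean(m[, "x1"]) - mean_b1), 0.05)
  expect_lt(abs(mean(m[, "x2"]) - mean_b2), 0.05)
  expect_lt(abs(sd(m[, "x1"]) - sd_b1), 0.04)
  expect_lt(abs(sd(m[, "x2"]) - sd_b2), 0.04)
})

test_that("latent scale indicator: degenerate and identical candidates", {
  set.seed(24)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + x))
  d <- data.frame(`v@100` = x, check.names = FALSE)
  d$used <- y; d$individual_id <- "a"; d$unit <- "a"; d$group <- NA_character_
  d <- structure(d, class = c("rsf_design", "data.frame"),
                 covariates = "v@100", ms_map = list(v = "v@100"),
                 alphas = numeric(0))
  fit <- fit_rsf(d, quick_config(iterations = 1000, burn_in = 500),
                 use_split = NULL)
  sp <- scale_probabilities(fit)
  expect_equal(sp$prob, 1)           # single candidate
  expect_equal(sum(sp$prob), 1)

  d2 <- d
  d2$`v@200` <- d2$`v@100`           # bit-identical candidate column
  attr(d2, "covariates") <- c("v@100", "v@200")
  attr(d2, "ms_map") <- list(v = c("v@100", "v@200"))
  fit2 <- fit_rsf(d2, quick_config(), use_split = NULL)
  sp2 <- scale_probabilities(fit2)
  expect_equal(sum(sp2$prob), 1)
  expect_true(all(abs(sp2$prob - 0.5) < 0.1))  # symmetric by construction
})

test_that("latent scale indicator recovers the generating radius", {
  set.seed(25)
  n <- 600
  x_true <- rnorm(n)     # the radius that truly drives selection
  x_decoy <- rnorm(n)    # well-separated (independent) alternative
  y <- rbinom(n, 1, plogis(-1 + 1.2 * x_true))
  d <- data.frame(`v@331` = x_decoy, `v@887` = x_true, check.names = FALSE)
  d$used <- y; d$individual_id <- "a"; d$unit <- "a"; d$group <- NA_character_
  d <- structure(d, class = c("rsf_design", "data.frame"),
                 covariates = c("v@331", "v@887"),
                 ms_map = list(v = c("v@331", "v@887")), alphas = numeric(0))
  fit <- fit_rsf(d, quick_config(), use_split = NULL)
  sp <- scale_probabilities(fit)
  expect_gt(sp$prob[sp$column == "v@887"], 0.9)
  expect_equal(sp$radius, c(331, 887))
  expect_equal(sp$column[sp$modal], "v@887")
})

test_that("two-stage fit refits at the modal scales with one column per variable", {
  set.seed(26)
  n <- 500
  x_true <- rnorm(n); x_decoy <- 0.3 * x_true + rnorm(n, 0, 0.5)
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 1.2 * x_true + 0.5 * z))
  d <- data.frame(z = z, `v@60` = x_decoy, `v@887` = x_true,
                  check.names = FALSE)
  d$used <- y; d$individual_id <- "a"; d$unit <- "a"; d$group <- NA_character_
  d <- structure(d, class = c("rsf_design", "data.frame"),
                 covariates = c("z", "v@60", "v@887"),
                 ms_map = list(v = c("v@60", "v@887")), alphas = numeric(0))
  ts <- two_stage_fit(d, quick_config())
  expect_equal(unname(ts$modal_scales["v"]), "v@887")
  expect_setequal(ts$fit$coef_names, c("z", "v"))
  expect_false("v@60" %in% names(ts$design))
  expect_equal(sum(ts$scale_posterior$prob), 1)
})

test_that("random intercepts are estimated and sigma respects its prior", {
  set.seed(27)
  J <- 15; nper <- 40
  ind <- rep(sprintf("b%02d", 1:J), each = nper)
  gam <- rnorm(J, 0, 0.8)
  x <- rnorm(J * nper)
  y <- rbinom(J * nper, 1, plogis(-1 + 0.8 * x + gam[as.integer(factor(ind))]))
  d <- data.frame(x1 = x)
  d$used <- y; d$individual_id <- ind; d$unit <- ind; d$group <- NA_character_
  d <- structure(d, class = c("rsf_design", "data.frame"),
                 covariates = "x1", ms_map = list(), alphas = numeric(0))
  fit <- fit_rsf(d, quick_config(random_intercept = TRUE), use_split = NULL)
  m <- as.matrix(fit)
  expect_true(all(m[, "sigma_gamma"] > 0 & m[, "sigma_gamma"] < 10))
  expect_gt(mean(m[, "sigma_gamma"]), 0.3)  # detects real heterogeneity
  expect_lt(abs(mean(m[, "x1"]) - 0.8), 0.2)
  g <- fit$chains[[1]]$gamma
  expect_equal(ncol(g), J)
  # individual-level intercepts track their generating values
  expect_gt(cor(colMeans(g), gam), 0.5)
})

test_that("influence flags follow the 85% sign-probability rule inclusively", {
  draws <- cbind("(Intercept)" = rnorm(1000),
                 pos = abs(rnorm(1000)) + 0.01,
                 sym = rnorm(1000),
                 edge = c(rep(1, 850), rep(-1, 150)))
  fake <- structure(list(chains = list(list(draws = draws)),
                         coef_names = c("pos", "sym", "edge")),
                    class = "rsf_posterior")
  fl <- influence_flags(fake)
  expect_true(fl$influential[fl$parameter == "pos"])
  expect_false(fl$influential[fl$parameter == "sym"])
  expect_true(fl$influential[fl$parameter == "edge"])  # exactly 0.85
})

test_that("group contrast pairs draws by iteration", {
  expect_equal(group_contrast(NULL, c(1, 2, 3), c(0, 1, 2)), 1)
  expect_equal(group_contrast(NULL, c(0, 1), c(1, 0)), 0.5)
  expect_error(group_contrast(NULL, 1:3, 1:4), "paired")
})

test_that("posterior summaries: median, degenerate and normal draws", {
  s <- posterior_summary(matrix(c(1, 2, 3), ncol = 1,
                                dimnames = list(NULL, "p")))
  expect_equal(s$median, 2)
  s0 <- posterior_summary(matrix(rep(7, 50), ncol = 1,
                                 dimnames = list(NULL, "p")))
  expect_equal(s0$lo95, s0$hi95)
  set.seed(28)
  sn <- posterior_summary(matrix(rnorm(1e5), ncol = 1,
                                 dimnames = list(NULL, "p")))
  expect_lt(abs(sn$lo95 + 1.96), 0.05)
  expect_lt(abs(sn$hi95 - 1.96), 0.05)
})
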