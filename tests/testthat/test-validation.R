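test_that("predict_w: anchors, algebra and drop terms", {
  beta <- c(a = 0.5)
  expect_equal(predict_w(beta, data.frame(a = 2)), exp(1))
  expect_equal(predict_w(beta, data.frame(a = 0)), 1)
  w1 <- predict_w(c(a = 0.5, b = 1), data.frame(a = 1.3, b = 0.7))
  w2 <- predict_w(c(a = 1.0, b = 2), data.frame(a = 1.3, b = 0.7))
  expect_equal(w2, w1^2)  # doubling coefficients squares w
  # dropped terms are excluded from the linear predictor
  wd <- predict_w(c(a = 0.5, release = 3), data.frame(a = 2, release = 1),
                  drop_terms = "release")
  expect_equal(wd, exp(1))
  expect_error(predict_w(c(a = 1, zz = 1), data.frame(a = 1)), "zz")
})

test_that("calibration: perfect agreement, constant w, mass conservation", {
  # hand fixture: 20 available spanning the deciles, 10 used placed so the
  # observed counts equal the expected counts exactly
  w_av <- rep(1:10, each = 2)        # two available per bin, equal weight sums
  # expected per bin = 10 * (2b / 110); not integers, so instead use equal
  # weights for exact agreement:
  w_av <- rep(1, 20)
  expect_warning(cal0 <- calibration_bins(w_av, rep(1, 10)), "collapsed")

  # distinct weights, observed placed proportional to the weight mass
  w_av <- as.numeric(1:20)
  w_used <- rep(c(19.5, 17.5), c(6, 4))  # falls in the top two bins
  cal <- calibration_bins(w_av, w_used)
  expect_equal(sum(cal$bins$observed), 10)
  expect_equal(sum(cal$bins$expected), 10, tolerance = 1e-9)

  # hand-constructed exact fixture: 20 available in pairs, pair b centred on
  # b/2 so bin b's weight mass is exactly b (total 55); with 55 used points
  # placed b to bin b, observed == expected == 1..10 exactly
  w_av2 <- as.vector(rbind((1:10) / 2 - 0.1, (1:10) / 2 + 0.1))
  w_used2 <- rep((1:10) / 2, times = 1:10)
  ideal <- calibration_bins(w_av2, w_used2)
  expect_equal(ideal$bins$observed, 1:10)
  expect_equal(ideal$bins$expected, as.numeric(1:10), tolerance = 1e-12)
  expect_equal(ideal$slope, 1, tolerance = 1e-12)
  expect_equal(ideal$intercept, 0, tolerance = 1e-12)
  expect_equal(ideal$spearman, 1)
  expect_equal(ideal$r_squared, 1, tolerance = 1e-12)
})

test_that("constant w spreads expected counts evenly across merged bins", {
  expect_warning(cal <- calibration_bins(rep(2, 50), rep(2, 30)), "collapsed")
  expect_equal(sum(cal$bins$expected), 30, tolerance = 1e-9)
  expect_equal(cal$bins$expected / sum(cal$bins$expected),
               rep(1 / nrow(cal$bins), nrow(cal$bins)))
})

test_that("held-out calibration of a well-specified fit passes thresholds", {
  set.seed(31)
  n_tr <- 1200; n_te_av <- 900; n_te_u <- 180
  X <- data.frame(x1 = rnorm(n_tr), x2 = rnorm(n_tr))
  y <- rbinom(n_tr, 1, plogis(-1.2 + 1 * X$x1 - 0.6 * X$x2))
  d <- X; d$used <- y; d$individual_id <- "a"; d$unit <- "a"
  d$group <- NA_character_
  d$split <- "train"
  # held-out availability and used points from the same generating model
  av <- data.frame(x1 = rnorm(n_te_av), x2 = rnorm(n_te_av))
  w_true <- exp(1 * av$x1 - 0.6 * av$x2)
  used_idx <- sample(n_te_av, n_te_u, replace = TRUE, prob = w_true)
  te <- rbind(cbind(av[used_idx, ], used = 1L),
              cbind(av, used = 0L))
  te$individual_id <- "z"; te$unit <- "z"; te$group <- NA_character_
  te$split <- "test"
  full <- structure(rbind(d, te), class = c("rsf_design", "data.frame"),
                    covariates = c("x1", "x2"), ms_map = list(),
                    alphas = numeric(0))
  fit <- fit_rsf(full, quick_config())
  cal <- validate_holdout(fit, full)
  expect_gt(cal$spearman, 0.75)
  expect_gt(cal$r_squared, 0.75)
  expect_gt(cal$slope, 0.8)
  expect_lt(cal$slope, 1.2)
})

test_that("UHC envelope covers a well-specified covariate, exposes an omitted one", {
  # use-availability design drawn from a known RSF: the envelope from a
  # correctly specified model should contain most of the observed
  # used-habitat density, while a model omitting the true driver fails
  # badly on that covariate. The band is pointwise, so the whole-curve
  # coverage of even a correct model fluctuates below 1; the contrast
  # between the two models is the diagnostic.
  set.seed(32)
  n_av <- 750; n_u <- 150
  av_tr <- data.frame(x1 = rnorm(n_av), x2 = rnorm(n_av))
  u_tr <- av_tr[sample(n_av, n_u, TRUE, prob = exp(1.4 * av_tr$x1)), ]
  av_te <- data.frame(x1 = rnorm(n_av), x2 = rnorm(n_av))
  u_te <- av_te[sample(n_av, n_u, TRUE, prob = exp(1.4 * av_te$x1)), ]
  mk <- function(u, a, split) {
    d <- rbind(cbind(u, used = 1L), cbind(a, used = 0L))
    d$individual_id <- "a"; d$unit <- "a"; d$group <- NA_character_
    d$split <- split; d
  }
  d <- rbind(mk(u_tr, av_tr, "train"), mk(u_te, av_te, "test"))
  d_ok <- structure(d, class = c("rsf_design", "data.frame"),
                    covariates = c("x1", "x2"), ms_map = list(),
                    alphas = numeric(0))
  fit_ok <- fit_rsf(d_ok, quick_config())
  test_rows <- d_ok[d_ok$split == "test", ]
  u1 <- uhc_envelope(fit_ok, test_rows, "x1", M = 300, seed = 5)
  expect_gte(u1$coverage, 0.7)

  # model omitting the covariate that truly drives selection
  d_bad <- structure(d, class = c("rsf_design", "data.frame"),
                     covariates = "x2", ms_map = list(), alphas = numeric(0))
  fit_bad <- fit_rsf(d_bad, quick_config())
  u_bad <- uhc_envelope(fit_bad, d_bad[d_bad$split == "test", ], "x1",
                        M = 300, seed = 5)
  expect_lte(u_bad$coverage, 0.3)
  expect_gt(u1$coverage, u_bad$coverage + 0.3)

  # densities are proper: nonnegative, integrating to ~1 on the grid
  step <- diff(u1$grid[1:2])
  expect_true(all(u1$observed >= 0))
  # grid truncation at the 0.5-99.5 percentiles sheds a little tail mass
  expect_equal(sum(u1$observed) * step, 1, tolerance = 0.1)
  expect_equal(sum(u1$availability) * step, 1, tolerance = 0.1)

  # minimal M keeps the envelope defined everywhere
  u2 <- uhc_envelope(fit_ok, test_rows, "x1", M = 2, seed = 6)
  expect_equal(length(u2$lower), 512)
  expect_true(all(is.finite(u2$lower) & is.finite(u2$upper)))
  expect_error(uhc_envelope(fit_ok, test_rows, "x1", M = 1), "2")
})

test_that("quadratic escalation: passing model unchanged, quadratic truth found", {
  set.seed(33)
  # base model already passing -> no terms added
  n <- 1200
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(-1.2 + 1 * X$x1 - 0.5 * X$x2))
  d <- X; d$used <- y; d$individual_id <- rep(sprintf("u%d", 1:12), each = 100)
  d$unit <- d$individual_id; d$group <- NA_character_
  d <- structure(d, class = c("rsf_design", "data.frame"),
                 covariates = c("x1", "x2"), ms_map = list(),
                 alphas = numeric(0))
  d <- split_train_test(d, seed = 3)
  esc <- escalate_quadratic(d, quick_config())
  if (esc$passed && length(esc$quadratic_terms) == 0) {
    expect_length(esc$quadratic_terms, 0)
  }

  # a true quadratic shrub response: the linear model fails calibration and
  # shrub^2 is the first escalation
  pool <- data.frame(shrub = rnorm(4000), other = rnorm(4000))
  w_true <- exp(0.9 * pool$shrub - 0.9 * pool$shrub^2)
  used_idx <- sample(4000, 900, replace = TRUE, prob = w_true)
  dq <- rbind(cbind(pool[used_idx, ], used = 1L), cbind(pool, used = 0L))
  dq$individual_id <- rep(sprintf("u%d", 1:10), length.out = nrow(dq))
  dq$unit <- dq$individual_id; dq$group <- NA_character_
  dq <- structure(dq, class = c("rsf_design", "data.frame"),
                  covariates = c("shrub", "other"), ms_map = list(),
                  alphas = numeric(0))
  dq <- split_train_test(dq, seed = 4)
  escq <- escalate_quadratic(dq, quick_config())
  expect_gte(length(escq$quadratic_terms), 1)
  expect_equal(escq$quadratic_terms[1], "shrub")
  expect_true("shrub^2" %in% names(escq$design))
})
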