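test_that("TRI: flat terrain, hand-computed centre, translation invariance", {
  flat <- raster_grid(matrix(5, 4, 4), cellsize = 30)
  expect_equal(compute_tri(flat)$values, matrix(0, 4, 4))

  bump <- raster_grid(matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3), cellsize = 30)
  expect_equal(compute_tri(bump)$values[2, 2], sqrt(8))

  set.seed(1)
  dem <- raster_grid(matrix(rnorm(64, 1000, 10), 8), cellsize = 30)
  dem2 <- dem; dem2$values <- dem$values + 100
  expect_equal(compute_tri(dem2)$values, compute_tri(dem)$values)
  expect_error(compute_tri(raster_grid(matrix(1, 2, 2))), "3x3")
})

test_that("aspect northness: north/south-dipping planes and flats", {
  ys <- matrix(rep(1:6, times = 6), 6)      # rows = south to north
  north_dip <- raster_grid(-30 * ys, cellsize = 30)  # falls northward
  expect_equal(compute_aspect_northness(north_dip)$values,
               matrix(1, 6, 6))
  south_dip <- raster_grid(30 * ys, cellsize = 30)
  expect_equal(compute_aspect_northness(south_dip)$values,
               matrix(-1, 6, 6))
  flat <- raster_grid(matrix(7, 5, 5), cellsize = 30)
  expect_equal(compute_aspect_northness(flat)$values, matrix(0, 5, 5))
})

test_that("slope: flat is 0, unit-gradient plane is 45 degrees", {
  flat <- raster_grid(matrix(7, 5, 5), cellsize = 30)
  expect_equal(compute_slope(flat)$values, matrix(0, 5, 5))
  xs <- matrix(rep(1:6, each = 6), 6)
  plane <- raster_grid(30 * xs, cellsize = 30)  # +30 m per 30 m east
  # interior cells see the exact unit gradient (edges use replicated cells)
  expect_equal(compute_slope(plane)$values[2:5, 2:5], matrix(45, 4, 4))
})

test_that("slope is screened out against ruggedness on rough terrain", {
  land <- tiny_landscape(seed = 3, nx = 40, ny = 40, smooth_range = 450)
  dem <- land$elevation
  cols <- data.frame(
    ruggedness = as.vector(compute_tri(dem)$values),
    elevation = as.vector(dem$values),
    slope = as.vector(compute_slope(dem)$values))
  expect_gt(abs(cor(cols$slope, cols$ruggedness)), 0.7)
  kept <- correlation_screen(cols, threshold = 0.7,
                             priority = c("ruggedness", "elevation", "slope"))
  expect_setequal(kept, c("ruggedness", "elevation"))
})

test_that("focal mean: constants, identity window, exact 5-cell window", {
  const <- raster_grid(matrix(3.5, 10, 10), cellsize = 30)
  expect_equal(focal_mean(const, 500)$values, const$values)
  set.seed(2)
  g <- raster_grid(matrix(rnorm(100), 10), cellsize = 30)
  expect_equal(focal_mean(g, 15)$values, g$values)  # radius < cell size

  v <- matrix(0, 7, 7); v[4, 4] <- 1
  spot <- raster_grid(v, cellsize = 30)
  out <- focal_mean(spot, 35)$values  # plus-shaped 5-cell window
  expect_equal(out[4, 4], 0.2)
  expect_equal(out[3, 4], 0.2)
  expect_equal(out[4, 5], 0.2)
  expect_equal(out[3, 3], 0)
})

test_that("focal mean matches the brute-force window oracle", {
  set.seed(4)
  v <- matrix(rnorm(30 * 20), 30, 20)
  v[sample(600, 15)] <- NA
  g <- raster_grid(v, cellsize = 30)
  brute <- function(g, radius) {
    nr <- nrow(g$values); nc <- ncol(g$values)
    out <- matrix(NA_real_, nr, nc)
    for (r in 1:nr) for (c in 1:nc) {
      vals <- c()
      for (rr in 1:nr) for (cc in 1:nc) {
        if (30 * sqrt((rr - r)^2 + (cc - c)^2) <= radius &&
            !is.na(g$values[rr, cc]))
          vals <- c(vals, g$values[rr, cc])
      }
      if (length(vals)) out[r, c] <- mean(vals)
    }
    out
  }
  for (radius in c(31, 95, 200)) {
    expect_equal(focal_mean(g, radius)$values, brute(g, radius),
                 tolerance = 1e-12)
  }
})

test_that("log ruggedness maps 0 to 0, e-1 to 1, and is monotone", {
  expect_equal(log_ruggedness(c(0, exp(1) - 1)), c(0, 1))
  x <- sort(runif(10, 0, 50))
  expect_true(all(diff(log_ruggedness(x)) > 0))
  expect_error(log_ruggedness(-1), "nonnegative")
})

test_that("distance grid: points, segments, minima, brute-force oracle", {
  g <- raster_grid(matrix(0, 10, 10), cellsize = 30)
  ctr <- grid_centers(g)
  # point on a cell centre -> that cell reads 0; 3 cells east reads 90
  d <- distance_grid(list(c(15, 15)), g)
  expect_equal(raster_extract(d, cbind(15, 15)), 0)
  expect_equal(raster_extract(d, cbind(105, 15)), 90)
  # two points: cellwise minimum
  d2 <- distance_grid(list(c(15, 15), c(285, 285)), g)
  da <- distance_grid(list(c(15, 15)), g)
  db <- distance_grid(list(c(285, 285)), g)
  expect_equal(d2$values, pmin(da$values, db$values))
  expect_error(distance_grid(list(), g), "empty")

  set.seed(5)
  feats <- list(c(40, 222), cbind(runif(4, 0, 300), runif(4, 0, 300)))
  dg <- distance_grid(feats, g)
  brute <- apply(ctr, 1, function(p) {
    best <- sqrt(sum((p - feats[[1]])^2))
    m <- feats[[2]]
    for (s in 1:3) {
      a <- m[s, ]; b <- m[s + 1, ]
      t <- max(0, min(1, sum((p - a) * (b - a)) / sum((b - a)^2)))
      best <- min(best, sqrt(sum((p - (a + t * (b - a)))^2)))
    }
    best
  })
  expect_equal(as.vector(dg$values), as.vector(brute), tolerance = 1e-12)
})

test_that("decay alpha: mean rule with the 6.4 km cap", {
  expect_equal(compute_alpha(c(1000, 3000)), 2000)
  expect_equal(compute_alpha(8200), 6400)       # cap binds
  expect_equal(compute_alpha(rep(6400, 5)), 6400)
  expect_error(compute_alpha(c(5, -1)), "nonnegative")
  expect_error(compute_alpha(numeric(0)), "no used")
})

test_that("decay transform: anchor values, range and monotonicity", {
  a <- 500
  expect_equal(decay_transform(0, a), 1)
  expect_equal(decay_transform(a, a), exp(-1))
  expect_equal(decay_transform(2 * a, a), exp(-2))
  d <- seq(0, 5000, by = 50)
  out <- decay_transform(d, a)
  expect_true(all(out > 0 & out <= 1))
  expect_true(all(diff(out) < 0))
  expect_error(decay_transform(-1, a), "nonnegative")
  expect_error(decay_transform(1, 0), "positive")
})

test_that("standardization: hand case, idempotence, leakage-free test rows", {
  st <- standardize(data.frame(a = c(1, 2, 3)))
  expect_equal(st$values$a, c(-1, 0, 1))   # sample-SD convention
  expect_equal(st$scaling$mean, 2)
  expect_equal(st$scaling$sd, 1)

  again <- standardize(st$values)
  expect_equal(again$values$a, st$values$a, tolerance = 1e-12)

  # scaling from reference rows applied verbatim elsewhere
  df <- data.frame(a = c(10, 20, 30, 20))
  st2 <- standardize(df, reference_rows = 1:3)
  expect_equal(st2$values$a[4], 0)  # equals the training mean
  expect_error(standardize(data.frame(a = c(1, 1, 1))), "zero-variance")

  set.seed(6)
  big <- data.frame(u = rnorm(500, 7, 3), v = runif(500))
  stb <- standardize(big)
  expect_lt(max(abs(colMeans(stb$values))), 1e-10)
  expect_lt(max(abs(vapply(stb$values, sd, 1) - 1)), 1e-10)
})

test_that("correlation screen keeps orthogonal columns, drops duplicates", {
  set.seed(7)
  x <- rnorm(100)
  cols <- data.frame(a = x, b = x, c = rnorm(100))
  expect_setequal(correlation_screen(cols, priority = c("a")), c("a", "c"))
  ortho <- data.frame(p = c(1, -1, 1, -1), q = c(1, 1, -1, -1),
                      r = c(1, -1, -1, 1))
  expect_setequal(correlation_screen(ortho), c("p", "q", "r"))
})

test_that("candidate radii: averaged min/mean/max with half-up rounding", {
  steps <- data.frame(
    individual_id = rep(c("a", "b"), each = 3),
    distance = c(100, 200, 300, 50, 150, 250))
  out <- compute_candidate_radii(steps, "brood")
  expect_equal(out$radii, c(75, 175, 275))
  summer <- compute_candidate_radii(steps, "summer")
  expect_equal(summer$radii, c(75, 138, 175, 275))  # 275/2 = 137.5 -> 138

  # averaged maximum of 3005 appends a 1503 m summer radius (half up)
  s2 <- data.frame(individual_id = rep(c("a", "b"), each = 1),
                   distance = c(3000, 3010))
  out2 <- compute_candidate_radii(s2, "summer")
  expect_true(1503 %in% out2$radii)

  one <- data.frame(individual_id = "a", distance = c(10, 20, 60))
  expect_equal(compute_candidate_radii(one, "nest")$radii, c(10, 30, 60))
})
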