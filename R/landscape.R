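#' Synthetic sagebrush landscape generator
#'
#' Builds a self-contained study landscape with the ingredients of a
#' sage-grouse habitat-selection analysis: spatially autocorrelated percent
#' shrub cover and elevation rasters, linear road and stream features, mesic
#' (wet meadow) centre points and a translocation release site. Every
#' downstream stage of the pipeline (covariates, design, model, maps) can be
#' exercised against this bundle with known generating truth.
#'
#' Autocorrelation is produced by circular moving-average smoothing of white
#' noise; `smooth_range` (m) controls the correlation range. With
#' `smooth_range = 0` the fields are raw (unsmoothed) noise.
#'
#' @param config a [landscape_config()] list.
#' @param seed integer seed; identical config + seed reproduce the landscape
#'   bit for bit.
#' @return A `landscape_bundle` list: raster grids `shrub`, `elevation`;
#'   vector features `roads`, `streams` (lists of polyline vertex matrices),
#'   `mesic_centers`, `release_sites` (point matrices); `cellsize`, `extent`,
#'   `seed`.
#' @export
generate_landscape <- function(config = landscape_config(), seed = 1) {
  cfg <- config
  if (cfg$cellsize <= 0) stop("cell size must be positive")
  if (cfg$nx < 3 || cfg$ny < 3) stop("degenerate extent: need at least 3x3 cells")
  set.seed(seed)

  shrub <- sim_field(cfg$ny, cfg$nx, cfg$cellsize, cfg$shrub_mean, cfg$shrub_sd,
                     cfg$smooth_range)
  shrub$values <- pmin(pmax(shrub$values, 0), 100)

  elev <- sim_field(cfg$ny, cfg$nx, cfg$cellsize, 0, cfg$elev_relief,
                    cfg$smooth_range)
  # gentle regional tilt so slope/aspect are non-degenerate
  ctr <- grid_centers(elev)
  tilt <- cfg$elev_tilt * (ctr[, 1] + 0.5 * ctr[, 2]) / (cfg$nx * cfg$cellsize)
  elev$values <- elev$values + cfg$elev_base + matrix(tilt, nrow = cfg$ny)

  w <- cfg$nx * cfg$cellsize
  h <- cfg$ny * cfg$cellsize
  # one road crossing east-west, one meandering stream south-north
  road_y <- stats::runif(1, 0.2, 0.8) * h
  roads <- list(cbind(x = c(0, 0.4 * w, w),
                      y = road_y + c(0, stats::runif(1, -0.1, 0.1) * h, 0)))
  stream_x <- stats::runif(1, 0.2, 0.8) * w
  sy <- seq(0, h, length.out = 8)
  streams <- list(cbind(x = stream_x + cumsum(stats::runif(8, -0.05, 0.05)) * w,
                        y = sy))
  mesic <- cbind(x = stats::runif(2, 0.15, 0.85) * w,
                 y = stats::runif(2, 0.15, 0.85) * h)
  release <- cbind(x = (0.5 + stats::runif(1, -0.05, 0.05)) * w,
                   y = (0.5 + stats::runif(1, -0.05, 0.05)) * h)

  structure(list(
    shrub = shrub, elevation = elev,
    roads = roads, streams = streams,
    mesic_centers = mesic, release_sites = release,
    cellsize = cfg$cellsize,
    extent = c(xmin = 0, xmax = w, ymin = 0, ymax = h),
    config = cfg, seed = seed
  ), class = "landscape_bundle")
}

#' @rdname generate_landscape
#' @param nx,ny grid dimensions in cells.
#' @param cellsize cell edge (m); 30 m matches standard DEM / rangeland
#'   cover products.
#' @param shrub_mean,shrub_sd percent shrub cover moments before clipping to
#'   \[0, 100\]; defaults emulate the low-cover northeastern range fringe.
#' @param smooth_range moving-average radius (m) controlling spatial
#'   autocorrelation; 0 disables smoothing.
#' @param elev_base,elev_relief,elev_tilt elevation (m): regional base, local
#'   relief SD and total cross-extent tilt.
#' @export
landscape_config <- function(nx = 120, ny = 120, cellsize = 30,
                             shrub_mean = 9, shrub_sd = 5,
                             smooth_range = 300,
                             elev_base = 950, elev_relief = 25,
                             elev_tilt = 60) {
  list(nx = as.integer(nx), ny = as.integer(ny), cellsize = cellsize,
       shrub_mean = shrub_mean, shrub_sd = shrub_sd,
       smooth_range = smooth_range, elev_base = elev_base,
       elev_relief = elev_relief, elev_tilt = elev_tilt)
}

# white noise at the target moments, smoothed, with variance restored
sim_field <- function(ny, nx, cellsize, mean, sd, smooth_range) {
  g <- raster_grid(matrix(stats::rnorm(ny * nx, mean, sd), nrow = ny),
                   cellsize = cellsize)
  smooth_field(g, smooth_range, restore_sd = sd)
}

#' Moving-average smoothing of a raster field
#'
#' Circular moving-average smoothing used by the landscape generator;
#' `range = 0` returns the input unchanged. When `restore_sd` is given the
#' smoothed field is rescaled back to that standard deviation around its mean
#' (smoothing alone would shrink the variance).
#'
#' @param g a [raster_grid()].
#' @param range smoothing radius in metres.
#' @param restore_sd optional target standard deviation after smoothing.
#' @return A [raster_grid()].
#' @export
smooth_field <- function(g, range, restore_sd = NULL) {
  if (range <= 0) return(g)
  sm <- focal_mean(g, range)
  if (!is.null(restore_sd)) {
    mu <- mean(sm$values)
    s <- stats::sd(as.vector(sm$values))
    if (s > 0) sm$values <- mu + (sm$values - mu) * (restore_sd / s)
  }
  sm
}

#' Two shrub-cover epochs with localized loss
#'
#' Derives a late-epoch shrub raster from the early epoch by subtracting a
#' smooth deficit that peaks at `loss_magnitude` percent cover at
#' `loss_center` and vanishes at and beyond `loss_radius` (a Wendland-style
#' bump, `loss_magnitude * (1 - (d/R)^2)^2` for `d < R`). This emulates
#' decades of shrub loss concentrated around the translocation release site.
#' The operation is deterministic given its inputs.
#'
#' @param landscape a `landscape_bundle`.
#' @param loss_center length-2 (x, y) inside the extent; defaults to the
#'   first release site.
#' @param loss_magnitude peak loss, percent cover in \[0, 100\].
#' @param loss_radius radius (m) beyond which cover is unchanged.
#' @return List with `early` and `late` [raster_grid()]s.
#' @export
generate_shrub_epochs <- function(landscape, loss_center = NULL,
                                  loss_magnitude = 6, loss_radius = 1000) {
  if (loss_radius <= 0) stop("loss_radius must be positive")
  if (loss_magnitude < 0 || loss_magnitude > 100)
    stop("loss_magnitude must lie in [0, 100]")
  if (is.null(loss_center)) loss_center <- landscape$release_sites[1, ]
  ext <- landscape$extent
  if (loss_center[1] < ext["xmin"] || loss_center[1] > ext["xmax"] ||
      loss_center[2] < ext["ymin"] || loss_center[2] > ext["ymax"])
    stop("loss_center lies outside the landscape extent")

  early <- landscape$shrub
  ctr <- grid_centers(early)
  d <- sqrt((ctr[, 1] - loss_center[1])^2 + (ctr[, 2] - loss_center[2])^2)
  u <- pmin(d / loss_radius, 1)
  deficit <- loss_magnitude * (1 - u^2)^2
  late <- early
  late$values <- pmin(pmax(early$values - matrix(deficit, nrow = nrow(early$values)), 0), 100)
  list(early = early, late = late)
}

#' Generating truth for synthetic telemetry
#'
#' Holds the parameters of the known resource selection function that
#' synthetic locations are drawn from: standardized selection coefficients
#' per covariate, the true focal radius per multi-scale covariate, the
#' between-individual intercept SD, and the exponential-decay ranges of the
#' distance covariates. Defaults mirror the qualitative pattern reported for
#' translocated sage-grouse (strong selection for shrub cover and proximity
#' to the release site, avoidance of rugged terrain and roads).
#'
#' @param beta named standardized coefficients; recognised names are
#'   `shrub`, `ruggedness`, `elevation`, `northness`, `road`, `water`,
#'   `mesic`, `release`.
#' @param true_scale named focal radii (m) for the multi-scale covariates.
#' @param re_sd SD of per-individual random intercepts (>= 0).
#' @param alpha named decay ranges (m) for distance covariates.
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(beta = c(shrub = 0.8, ruggedness = -0.6,
                                      elevation = -0.4, northness = 0.2,
                                      road = -0.3, water = -0.2,
                                      mesic = 0.4, release = 1.0),
                             true_scale = c(shrub = 887, ruggedness = 887),
                             re_sd = 0.3,
                             alpha = c(road = 800, water = 800,
                                       mesic = 800, release = 800)) {
  if (re_sd < 0) stop("re_sd must be nonnegative")
  structure(list(beta = beta, true_scale = true_scale, re_sd = re_sd,
                 alpha = alpha),
            class = "simulation_truth")
}

# Cell-level covariate matrix on the generating (truth) scales, standardized
# over all cells. Returns list(X = matrix n_cells x k, centers, names).
truth_covariates <- function(landscape, truth, shrub = landscape$shrub) {
  ctr <- grid_centers(shrub)
  cols <- list()
  nm <- names(truth$beta)

  if ("shrub" %in% nm) {
    g <- smooth_field(shrub, truth$true_scale[["shrub"]])
    cols$shrub <- as.vector(g$values)
  }
  if ("elevation" %in% nm) cols$elevation <- as.vector(landscape$elevation$values)
  if ("ruggedness" %in% nm) {
    tri <- compute_tri(landscape$elevation)
    lr <- smooth_field(log_ruggedness(tri), truth$true_scale[["ruggedness"]])
    cols$ruggedness <- as.vector(lr$values)
  }
  if ("northness" %in% nm)
    cols$northness <- as.vector(compute_aspect_northness(landscape$elevation)$values)
  feat <- list(road = landscape$roads, water = landscape$streams,
               mesic = list(landscape$mesic_centers),
               release = list(landscape$release_sites))
  for (f in intersect(names(feat), nm)) {
    dg <- distance_grid(feat[[f]], shrub)
    cols[[f]] <- exp(-as.vector(dg$values) / truth$alpha[[f]])
  }
  X <- do.call(cbind, cols[nm])
  X <- scale(X)  # population of cells defines the standardized scale
  X[, !is.finite(colSums(X))] <- 0  # constant columns carry no selection signal
  list(X = X, centers = ctr)
}

# sample n cells with probability proportional to exp(X beta + offset),
# jitter uniformly within the cell
draw_locations <- function(landscape, Xinfo, beta, offset, n) {
  lp <- as.vector(Xinfo$X %*% beta) + offset
  w <- exp(lp - max(lp))
  if (!all(is.finite(w)) || sum(w) <= 0)
    stop("cell weights are zero or non-finite; check the generating coefficients")
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  half <- landscape$cellsize / 2
  cbind(x = Xinfo$centers[idx, 1] + stats::runif(n, -half, half),
        y = Xinfo$centers[idx, 2] + stats::runif(n, -half, half))
}

#' Simulate daily telemetry locations from the generating RSF
#'
#' Each individual receives a Normal(0, `re_sd`^2) random intercept; each of
#' its daily locations is an independent draw of a raster cell with
#' probability proportional to `exp(x' beta + gamma_j)` (covariates at the
#' true scales, including the release-site decay term), jittered uniformly
#' within the cell. Locations are independent day to day — daily step
#' distances are still well defined and feed the candidate-radius rule.
#'
#' @param landscape a `landscape_bundle`.
#' @param truth a [simulation_truth()].
#' @param n_individuals,days_per_individual study size.
#' @param seed integer seed.
#' @param life_stage label attached to the rows (`"brood"` or `"summer"`).
#' @param start_date first tracking day.
#' @return A `data.frame` location table: `individual_id`, `date`, `x`, `y`,
#'   `life_stage`, `group`, `year`, `used`.
#' @export
simulate_individuals <- function(landscape, truth, n_individuals = 30,
                                 days_per_individual = 5, seed = 1,
                                 life_stage = "brood",
                                 start_date = as.Date("2017-06-01")) {
  if (n_individuals < 1) stop("need at least one individual")
  set.seed(seed)
  Xinfo <- truth_covariates(landscape, truth)
  gam <- stats::rnorm(n_individuals, 0, truth$re_sd)
  out <- vector("list", n_individuals)
  for (j in seq_len(n_individuals)) {
    xy <- draw_locations(landscape, Xinfo, truth$beta, gam[j],
                         days_per_individual)
    out[[j]] <- data.frame(
      individual_id = sprintf("ind%02d", j),
      date = start_date + seq_len(days_per_individual) - 1L,
      x = xy[, 1], y = xy[, 2],
      life_stage = life_stage, group = NA_character_,
      year = as.integer(format(start_date, "%Y")), used = 1L)
  }
  do.call(rbind, out)
}

#' Simulate nest locations for two origin groups
#'
#' One used point per nest, drawn as in [simulate_individuals()] but without
#' random intercepts; each group (`resident`, `translocated`) can have its
#' own generating coefficients, supporting the posterior contrast of
#' selection between prior residents and translocated females. Default group
#' sizes pool 44 resident and 17 translocated nests (61 total) across the
#' years 2005/2007 and 2017/2018.
#'
#' @param landscape a `landscape_bundle`.
#' @param truth a [simulation_truth()] providing scales and decay ranges.
#' @param n_per_group named integer vector over `resident`, `translocated`.
#' @param group_betas named list of coefficient vectors, one per group;
#'   defaults to `truth$beta` for both.
#' @param seed integer seed.
#' @return A nest location table (one row per nest, `used = 1`).
#' @export
simulate_nests <- function(landscape, truth,
                           n_per_group = c(resident = 44, translocated = 17),
                           group_betas = NULL, seed = 1) {
  if (!all(names(n_per_group) %in% c("resident", "translocated")))
    stop("group tags must be 'resident' or 'translocated'")
  if (is.null(group_betas))
    group_betas <- stats::setNames(rep(list(truth$beta), length(n_per_group)),
                                   names(n_per_group))
  if (!all(names(n_per_group) %in% names(group_betas)))
    stop("each group needs a coefficient set")
  set.seed(seed)
  Xinfo <- truth_covariates(landscape, truth)
  years <- list(resident = c(2005L, 2007L), translocated = c(2017L, 2018L))
  out <- list()
  for (grp in names(n_per_group)) {
    n <- n_per_group[[grp]]
    if (n < 1) next
    xy <- draw_locations(landscape, Xinfo, group_betas[[grp]], 0, n)
    yr <- rep(years[[grp]], length.out = n)
    out[[grp]] <- data.frame(
      individual_id = sprintf("%s_nest%02d", grp, seq_len(n)),
      date = as.Date(paste0(yr, "-05-15")),
      x = xy[, 1], y = xy[, 2],
      life_stage = "nest", group = grp, year = yr, used = 1L)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-individual daily step distances
#'
#' Euclidean distances between consecutive-day locations of each individual
#' (rows sorted by date). Each individual with `d` locations contributes
#' `d - 1` steps.
#'
#' @param locations a location table from [simulate_individuals()].
#' @return `data.frame` with `individual_id` and `distance` (m).
#' @export
step_distances <- function(locations) {
  sp <- split(locations[order(locations$date), ], locations$individual_id)
  out <- lapply(names(sp), function(id) {
    p <- sp[[id]]
    if (nrow(p) < 2) return(NULL)
    data.frame(individual_id = id,
               distance = sqrt(diff(p$x)^2 + diff(p$y)^2))
  })
  do.call(rbind, out)
}

#' Write a landscape bundle to disk
#'
#' Grids as ESRI ASCII (`.asc`), vector features as GeoJSON.
#'
#' @param landscape a `landscape_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_ascii_grid(landscape$shrub, file.path(dir, "shrub.asc"))
  write_ascii_grid(landscape$elevation, file.path(dir, "elevation.asc"))
  write_geojson(landscape[c("roads", "streams", "mesic_centers",
                            "release_sites")],
                file.path(dir, "features.geojson"))
  invisible(dir)
}
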