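#' Thin telemetry to one location per individual-day
#'
#' Keeps exactly one row per (individual, date), chosen uniformly at random,
#' to avoid spatial dependence between fixes collected close together in
#' time. Idempotent on already-thinned tables.
#'
#' @param locations a location table with `individual_id` and `date`.
#' @param seed integer seed.
#' @return The thinned location table.
#' @export
thin_one_per_day <- function(locations, seed = 1) {
  if (any(is.na(locations$date))) stop("locations with missing dates")
  set.seed(seed)
  key <- interaction(locations$individual_id, locations$date, drop = TRUE)
  pick <- unlist(lapply(split(seq_len(nrow(locations)), key), function(ix)
    if (length(ix) == 1L) ix else sample(ix, 1L)), use.names = FALSE)
  locations[sort(pick), , drop = FALSE]
}

#' Drop individuals with too few locations
#'
#' Brood-rearing individuals need at least 5 thinned locations, summer
#' individuals at least 10; nests are single points and pass unfiltered.
#'
#' @param locations a thinned location table.
#' @param life_stage `"nest"`, `"brood"` or `"summer"`.
#' @return The filtered table (possibly empty, with a warning).
#' @export
filter_min_locations <- function(locations, life_stage = c("brood", "nest", "summer")) {
  life_stage <- match.arg(life_stage)
  min_n <- switch(life_stage, nest = 1L, brood = 5L, summer = 10L)
  counts <- table(locations$individual_id)
  keep <- names(counts)[counts >= min_n]
  out <- locations[locations$individual_id %in% keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no individuals meet the minimum-location rule")
  out
}

#' Minimum convex polygon of used locations
#'
#' Convex hull of the used coordinates; the availability/study boundary.
#'
#' @param locations a location table (its `x`, `y` columns are used) or a
#'   two-column coordinate matrix.
#' @return Matrix of hull vertices (counter-clockwise, not closed), class
#'   `mcp_boundary`.
#' @export
mcp_boundary <- function(locations) {
  xy <- if (is.data.frame(locations) && all(c("x", "y") %in% names(locations)))
    cbind(locations$x, locations$y) else as.matrix(locations)[, 1:2]
  xy <- unique(xy)
  if (nrow(xy) < 3) stop("need at least 3 distinct points for an MCP")
  h <- rev(grDevices::chull(xy))  # counter-clockwise
  poly <- xy[h, , drop = FALSE]
  colnames(poly) <- c("x", "y")
  if (polygon_area(poly) <= 0) stop("points are collinear; MCP is degenerate")
  structure(poly, class = c("mcp_boundary", class(poly)))
}

#' Polygon area (shoelace formula)
#' @param poly vertex matrix (closed or open ring).
#' @return Area in squared map units.
#' @export
polygon_area <- function(poly) {
  p <- as.matrix(poly)[, 1:2, drop = FALSE]
  if (all(p[1, ] == p[nrow(p), ]) && nrow(p) > 1) p <- p[-nrow(p), , drop = FALSE]
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

points_in_polygon <- function(poly, xy) {
  p <- as.matrix(poly)[, 1:2, drop = FALSE]
  mgcv::in.out(rbind(p, p[1, ]), as.matrix(xy)[, 1:2, drop = FALSE])
}

#' Uniform availability sample within the study boundary
#'
#' Draws `ratio` random points per used location, uniformly over the MCP by
#' rejection sampling from its bounding box. Returned in order: the first
#' `ratio` points pair with the first used location, and so on, which is how
#' [assemble_design()] assigns availability to sampling units.
#'
#' @param boundary an [mcp_boundary()] (or vertex matrix).
#' @param n_used number of used locations.
#' @param ratio available points per used point.
#' @param seed integer seed.
#' @return Matrix of `ratio * n_used` points (columns `x`, `y`).
#' @export
sample_available <- function(boundary, n_used, ratio = 5, seed = 1) {
  if (n_used < 1) stop("n_used must be at least 1")
  if (polygon_area(boundary) <= 0) stop("degenerate boundary polygon")
  set.seed(seed)
  n <- n_used * ratio
  p <- as.matrix(boundary)[, 1:2, drop = FALSE]
  bb <- c(range(p[, 1]), range(p[, 2]))
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 100L)
    cand <- cbind(stats::runif(m, bb[1], bb[2]), stats::runif(m, bb[3], bb[4]))
    out <- rbind(out, cand[points_in_polygon(boundary, cand), , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Covariate stack for design assembly and surface prediction
#'
#' Derives every model covariate grid from a landscape bundle: elevation,
#' northness, slope, log-ruggedness focal-smoothed at each candidate radius,
#' shrub cover smoothed at each candidate radius, and raw distance grids for
#' roads, waterways, mesic centres and release sites (decay-transformed later
#' with alphas estimated from used locations). Multi-scale columns are named
#' `var@radius`.
#'
#' @param landscape a `landscape_bundle`.
#' @param radii candidate focal radii in metres.
#' @param shrub optional replacement shrub [raster_grid()] (e.g. another
#'   epoch); defaults to the bundle's.
#' @param include_slope include the slope grid (for the collinearity screen).
#' @return List: `grids` (named list of [raster_grid()]), `ms_map` (named
#'   list, multi-scale variable -> its column names), `decay_vars` (names of
#'   raw-distance grids).
#' @export
build_covariate_stack <- function(landscape, radii = c(60, 331, 887),
                                  shrub = NULL, include_slope = FALSE) {
  if (is.null(shrub)) shrub <- landscape$shrub
  dem <- landscape$elevation
  grids <- list(elevation = dem,
                northness = compute_aspect_northness(dem))
  if (include_slope) grids$slope <- compute_slope(dem)
  logtri <- log_ruggedness(compute_tri(dem))
  ms_map <- list(shrub = character(0), ruggedness = character(0))
  for (r in radii) {
    sn <- sprintf("shrub@%d", r)
    rn <- sprintf("ruggedness@%d", r)
    grids[[sn]] <- smooth_field(shrub, r)
    grids[[rn]] <- smooth_field(logtri, r)
    ms_map$shrub <- c(ms_map$shrub, sn)
    ms_map$ruggedness <- c(ms_map$ruggedness, rn)
  }
  feat <- list(road = landscape$roads, water = landscape$streams,
               mesic = list(landscape$mesic_centers),
               release = list(landscape$release_sites))
  for (f in names(feat)) grids[[f]] <- distance_grid(feat[[f]], shrub)
  list(grids = grids, ms_map = ms_map, decay_vars = names(feat))
}

#' Assemble the used/available design matrix
#'
#' Attaches covariates to used and available points (value of the cell
#' containing each point), converts raw distance covariates to exponential
#' decays with alpha estimated from the used rows ([compute_alpha()]), and
#' labels each row with its sampling unit (the individual for brood/summer
#' data, the nest for nest data) so that train/test splits are leak-free.
#' Availability rows inherit the unit of their paired used row, keeping the
#' 5:1 ratio exact within every unit and split partition. Rows falling on
#' nodata cells are dropped with a reported count.
#'
#' Standardization is deliberately deferred to [standardize_design()], which
#' runs after [split_train_test()] so that scaling statistics come from
#' training rows only.
#'
#' @param used used-location table (`x`, `y`, `individual_id`, `life_stage`,
#'   `group`, `year`).
#' @param available availability points from [sample_available()].
#' @param stack covariate stack from [build_covariate_stack()].
#' @param alpha_cap cap (m) for decay alphas.
#' @return An `rsf_design` data frame: `used` response, covariate columns,
#'   `individual_id`, `unit`, plus `ms_map` / `alphas` attributes.
#' @export
assemble_design <- function(used, available, stack, alpha_cap = 6400) {
  n_used <- nrow(used)
  ratio <- nrow(available) / n_used
  if (ratio != round(ratio))
    stop("available rows must be an exact multiple of used rows")
  # the sampling unit is the individual (each nest has its own id)
  unit_of_used <- used$individual_id
  # availability pairs with used rows in blocks
  pair <- rep(seq_len(n_used), each = ratio)

  xy <- rbind(cbind(used$x, used$y), as.matrix(available)[, 1:2])
  cov <- lapply(stack$grids, raster_extract, xy = xy)
  cov <- as.data.frame(cov, check.names = FALSE, optional = TRUE)
  names(cov) <- names(stack$grids)

  y <- c(rep(1L, n_used), rep(0L, nrow(available)))
  ind <- c(used$individual_id, used$individual_id[pair])
  unit <- c(unit_of_used, unit_of_used[pair])
  grp <- c(as.character(used$group), as.character(used$group)[pair])
  yr <- c(used$year, used$year[pair])

  ok <- stats::complete.cases(cov)
  if (any(!ok)) {
    message(sum(!ok), " row(s) on nodata cells dropped")
    drop_used <- which(!ok[seq_len(n_used)])
    if (length(drop_used)) {
      ok[n_used + which(pair %in% drop_used)] <- FALSE
    }
  }

  alphas <- numeric(0)
  for (f in stack$decay_vars) {
    a <- compute_alpha(cov[[f]][seq_len(n_used)][ok[seq_len(n_used)]], cap = alpha_cap)
    alphas[f] <- a
    cov[[f]] <- decay_transform(cov[[f]], a)
  }

  out <- data.frame(used = y, x = xy[, 1], y_coord = xy[, 2],
                    individual_id = ind, unit = unit, group = grp, year = yr,
                    stringsAsFactors = FALSE)
  out <- cbind(out, cov)
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("rsf_design", "data.frame"),
            covariates = names(cov),
            ms_map = stack$ms_map,
            alphas = alphas)
}

#' Train/test split by sampling unit
#'
#' Randomly assigns about two thirds of the sampling units (nests, or
#' individuals for brood/summer data) to training and the rest to testing;
#' every row of a unit — used and its paired availability — shares the tag,
#' so no unit leaks across the partition and the 5:1 ratio holds within each.
#'
#' @param design an `rsf_design` from [assemble_design()].
#' @param fraction_train fraction of units assigned to training.
#' @param seed integer seed.
#' @return The design with a `split` column (`"train"` / `"test"`).
#' @export
split_train_test <- function(design, fraction_train = 2 / 3, seed = 1) {
  units <- unique(design$unit)
  if (length(units) < 3) stop("need at least 3 units to split")
  set.seed(seed)
  n_train <- round_half_up(fraction_train * length(units))
  if (n_train < 2 || length(units) - n_train < 2)
    stop("split leaves fewer than 2 units in a partition")
  train_units <- sample(units, n_train)
  design$split <- ifelse(design$unit %in% train_units, "train", "test")
  design
}

#' Standardize design covariates on training rows
#'
#' Applies [standardize()] to every covariate column using training rows as
#' the reference (all rows when no split tag exists) and stores the scaling
#' record as the `scaling` attribute for later use on test rows and
#' prediction grids.
#'
#' @param design an `rsf_design`, normally after [split_train_test()].
#' @return The standardized design.
#' @export
standardize_design <- function(design) {
  covs <- attr(design, "covariates")
  ref <- if ("split" %in% names(design)) which(design$split == "train")
         else seq_len(nrow(design))
  # a focal radius wider than the study area (or any other degenerate
  # covariate) yields a constant column: uninformative, dropped with notice
  sds <- vapply(design[ref, covs, drop = FALSE], stats::sd, numeric(1))
  flat <- covs[!is.finite(sds) | sds == 0]
  if (length(flat)) {
    message("dropping constant covariate column(s): ",
            paste(flat, collapse = ", "))
    covs <- setdiff(covs, flat)
    design[flat] <- NULL
    attr(design, "covariates") <- covs
    ms <- attr(design, "ms_map")
    attr(design, "ms_map") <- lapply(ms, setdiff, y = flat)
  }
  st <- standardize(design[, covs, drop = FALSE], ref)
  design[, covs] <- st$values
  attr(design, "scaling") <- st$scaling
  design
}

#' @export
print.rsf_design <- function(x, ...) {
  cat(sprintf("<rsf_design> %d rows (%d used, %d available), %d covariates\n",
              nrow(x), sum(x$used == 1), sum(x$used == 0),
              length(attr(x, "covariates"))))
  if ("split" %in% names(x))
    cat(sprintf("  split: %d train / %d test rows\n",
                sum(x$split == "train"), sum(x$split == "test")))
  ms <- attr(x, "ms_map")
  if (length(ms))
    cat("  multi-scale:", paste(names(ms), collapse = ", "), "\n")
  invisible(x)
}

# covariate columns that are not multi-scale candidates
single_scale_covariates <- function(design) {
  setdiff(attr(design, "covariates"), unlist(attr(design, "ms_map")))
}
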