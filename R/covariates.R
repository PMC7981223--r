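#' Terrain ruggedness index (TRI)
#'
#' Per cell, the square root of the summed squared elevation differences
#' between the cell and its eight neighbours. Border cells use the neighbours
#' that exist, so edge cells stay defined; a cell whose whole neighbourhood
#' is nodata yields nodata. TRI is invariant to adding a constant to the DEM.
#'
#' @param dem elevation [raster_grid()] (m).
#' @return A [raster_grid()] of TRI values.
#' @export
compute_tri <- function(dem) {
  v <- dem$values
  if (nrow(v) < 3 || ncol(v) < 3) stop("DEM must be at least 3x3")
  nr <- nrow(v); nc <- ncol(v)
  ss <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    nb <- v[rs - dr, cs - dc, drop = FALSE]
    ce <- v[rs, cs, drop = FALSE]
    d2 <- (nb - ce)^2
    ok <- !is.na(d2)
    d2[!ok] <- 0
    ss[rs, cs] <- ss[rs, cs] + d2
    cnt[rs, cs] <- cnt[rs, cs] + ok
  }
  out <- sqrt(ss)
  out[cnt == 0L | is.na(v)] <- NA
  raster_grid(out, dem$xmin, dem$ymin, dem$cellsize)
}

# Horn (3rd-order finite difference) gradients on an edge-replicated DEM.
# Returns list(dzdx east+, dzdy north+). Row 1 is the southernmost row.
horn_gradients <- function(dem) {
  v <- dem$values
  if (nrow(v) < 3 || ncol(v) < 3) stop("DEM must be at least 3x3")
  nr <- nrow(v); nc <- ncol(v)
  pad <- rbind(v[1, , drop = FALSE], v, v[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  sh <- function(dr, dc) pad[(1:nr) + 1 + dr, (1:nc) + 1 + dc, drop = FALSE]
  # compass neighbours; north = increasing row
  nw <- sh(1, -1); n_ <- sh(1, 0); ne <- sh(1, 1)
  w_ <- sh(0, -1);                 e_ <- sh(0, 1)
  sw <- sh(-1, -1); s_ <- sh(-1, 0); se <- sh(-1, 1)
  cs <- dem$cellsize
  list(dzdx = ((ne + 2 * e_ + se) - (nw + 2 * w_ + sw)) / (8 * cs),
       dzdy = ((nw + 2 * n_ + ne) - (sw + 2 * s_ + se)) / (8 * cs))
}

#' Slope in degrees (Horn's method)
#'
#' Computed chiefly to feed the collinearity screen, which is expected to
#' drop it in favour of ruggedness and elevation.
#'
#' @param dem elevation [raster_grid()].
#' @return A [raster_grid()] of slope in degrees.
#' @export
compute_slope <- function(dem) {
  g <- horn_gradients(dem)
  raster_grid(atan(sqrt(g$dzdx^2 + g$dzdy^2)) * 180 / pi,
              dem$xmin, dem$ymin, dem$cellsize)
}

#' Aspect as northness
#'
#' Aspect is the compass direction of steepest descent (Horn finite
#' differences); its cosine ("northness", in \[-1, 1\]) enters the linear
#' predictor, since a raw circular degree cannot. A plane dipping due north
#' has northness 1, dipping due south -1; flat cells are 0 by convention.
#'
#' @param dem elevation [raster_grid()].
#' @return A [raster_grid()] of northness values.
#' @export
compute_aspect_northness <- function(dem) {
  g <- horn_gradients(dem)
  mag <- sqrt(g$dzdx^2 + g$dzdy^2)
  north <- ifelse(mag > 0, -g$dzdy / mag, 0)
  north[is.na(dem$values)] <- NA
  raster_grid(north, dem$xmin, dem$ymin, dem$cellsize)
}

#' Circular moving-window (focal) mean
#'
#' Per cell, the mean over all valid cells whose centres lie within `radius`
#' metres of the target cell centre; the centre cell is always a member. The
#' window shrinks at grid edges and around nodata cells. A radius smaller
#' than the cell size reduces to the identity.
#'
#' @param grid a [raster_grid()].
#' @param radius window radius in metres (> 0).
#' @return A [raster_grid()] of focal means.
#' @export
focal_mean <- function(grid, radius) {
  if (radius <= 0) stop("radius must be positive")
  k <- floor(radius / grid$cellsize)
  offs <- expand.grid(dr = -k:k, dc = -k:k)
  offs <- offs[grid$cellsize * sqrt(offs$dr^2 + offs$dc^2) <= radius, ,
               drop = FALSE]
  out <- focal_mean_cpp(grid$values, as.matrix(offs))
  raster_grid(out, grid$xmin, grid$ymin, grid$cellsize)
}

#' Log-transformed ruggedness
#'
#' `log(TRI + 1)`: keeps TRI = 0 mapped to 0 and is monotone. Focal
#' smoothing of ruggedness is applied after this transform.
#'
#' @param tri a TRI [raster_grid()] (or numeric vector), all values >= 0.
#' @return Same shape as the input.
#' @export
log_ruggedness <- function(tri) {
  v <- if (inherits(tri, "raster_grid")) tri$values else tri
  if (any(v < 0, na.rm = TRUE)) stop("ruggedness must be nonnegative")
  out <- log(v + 1)
  if (inherits(tri, "raster_grid"))
    raster_grid(out, tri$xmin, tri$ymin, tri$cellsize)
  else out
}

#' Euclidean distance to the nearest feature
#'
#' Distance (m) from each cell centre to the nearest geometry in a feature
#' set: exact point distance for points (including mesic-area centroids) and
#' segment-wise distance for polyline vertices.
#'
#' @param features list of geometries; each element is either a length-2
#'   numeric (a point), a matrix with one row (a point), or a matrix of >= 2
#'   polyline vertices.
#' @param template [raster_grid()] supplying the output geometry.
#' @return A [raster_grid()] of distances in metres.
#' @export
distance_grid <- function(features, template) {
  if (length(features) == 0) stop("feature set is empty")
  ctr <- grid_centers(template)
  d <- rep(Inf, nrow(ctr))
  for (f in features) {
    m <- if (is.matrix(f) || is.data.frame(f)) as.matrix(f) else matrix(f, nrow = 1)
    if (nrow(m) == 1) {
      d <- pmin(d, sqrt((ctr[, 1] - m[1, 1])^2 + (ctr[, 2] - m[1, 2])^2))
    } else {
      for (s in seq_len(nrow(m) - 1))
        d <- pmin(d, dist_point_segment(ctr, m[s, 1:2], m[s + 1, 1:2]))
      # lone vertices of degenerate zero-length segments are still covered
    }
  }
  raster_grid(matrix(d, nrow = nrow(template$values)),
              template$xmin, template$ymin, template$cellsize)
}

# vectorized point-to-segment distance
dist_point_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((p[, 1] - a[1])^2 + (p[, 2] - a[2])^2))
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((p[, 1] - (a[1] + t * ab[1]))^2 + (p[, 2] - (a[2] + t * ab[2]))^2)
}

#' Decay range for a distance covariate
#'
#' The exponential-decay range alpha is the mean distance to the feature over
#' all used locations, capped at 6,400 m, whichever is smaller.
#'
#' @param used_distances distances (m) at used locations; nonnegative.
#' @param cap upper bound in metres.
#' @return alpha in metres.
#' @export
compute_alpha <- function(used_distances, cap = 6400) {
  if (length(used_distances) == 0) stop("no used distances supplied")
  if (any(used_distances < 0)) stop("distances must be nonnegative")
  min(mean(used_distances), cap)
}

#' Exponential distance decay
#'
#' `exp(-d / alpha)`, in (0, 1\], strictly decreasing in distance, so that
#' feature effects fade with distance.
#'
#' @param dist distances: a [raster_grid()] or numeric vector (m, >= 0).
#' @param alpha decay range (m, > 0).
#' @return Same shape as `dist`.
#' @export
decay_transform <- function(dist, alpha) {
  if (alpha <= 0) stop("alpha must be positive")
  v <- if (inherits(dist, "raster_grid")) dist$values else dist
  if (any(v < 0, na.rm = TRUE)) stop("distances must be nonnegative")
  out <- exp(-v / alpha)
  if (inherits(dist, "raster_grid"))
    raster_grid(out, dist$xmin, dist$ymin, dist$cellsize)
  else out
}

#' Standardize columns against reference rows
#'
#' Centres and scales each column to mean 0, SD 1 using statistics computed
#' on the reference rows only (training used + available); the returned
#' scaling record is reapplied verbatim to held-out rows and to prediction
#' grids, so no information leaks from test data into the transform. The
#' sample (n - 1) standard deviation is used.
#'
#' @param columns data frame or matrix of numeric columns.
#' @param reference_rows integer or logical index of the rows defining the
#'   statistics; default all rows.
#' @return List: `values` (standardized columns, same shape) and `scaling`
#'   (`data.frame` with `column`, `mean`, `sd`).
#' @export
standardize <- function(columns, reference_rows = seq_len(nrow(columns))) {
  columns <- as.data.frame(columns)
  ref <- columns[reference_rows, , drop = FALSE]
  mu <- vapply(ref, mean, numeric(1))
  sdv <- vapply(ref, stats::sd, numeric(1))
  bad <- names(columns)[!is.finite(sdv) | sdv == 0]
  if (length(bad))
    stop("zero-variance column(s) on reference rows: ", paste(bad, collapse = ", "))
  scaling <- data.frame(column = names(columns), mean = unname(mu),
                        sd = unname(sdv), stringsAsFactors = FALSE)
  list(values = apply_scaling(columns, scaling), scaling = scaling)
}

#' @rdname standardize
#' @param scaling a scaling record from [standardize()].
#' @export
apply_scaling <- function(columns, scaling) {
  columns <- as.data.frame(columns)
  for (i in seq_len(nrow(scaling))) {
    cn <- scaling$column[i]
    if (!cn %in% names(columns)) stop("scaling record mismatch: missing column ", cn)
    columns[[cn]] <- (columns[[cn]] - scaling$mean[i]) / scaling$sd[i]
  }
  columns
}

#' Pairwise collinearity screen
#'
#' Greedy Pearson screen: for each column pair with `|r|` above the
#' threshold, the lower-priority member is dropped. The default priority
#' order ranks ruggedness and elevation above slope, so on rough terrain
#' (where slope and TRI are strongly collinear) slope is the variable
#' removed.
#'
#' @param columns data frame of candidate columns.
#' @param threshold absolute Pearson correlation above which a pair conflicts.
#' @param priority character vector, highest priority first; unlisted columns
#'   rank below listed ones in input order.
#' @return Character vector of retained column names.
#' @export
correlation_screen <- function(columns, threshold = 0.7, priority = NULL) {
  columns <- as.data.frame(columns)
  nms <- names(columns)
  if (length(nms) < 2) stop("need at least two columns to screen")
  rank <- rep(Inf, length(nms))
  if (!is.null(priority))
    rank[match(intersect(priority, nms), nms)] <-
      match(intersect(priority, nms), priority)
  ord <- order(rank, seq_along(nms))
  keep <- rep(TRUE, length(nms))
  cm <- stats::cor(columns)
  for (i in seq_along(ord)) {
    hi <- ord[i]
    if (!keep[hi]) next
    for (j in seq_along(ord)) {
      lo <- ord[j]
      if (j <= i || !keep[lo]) next
      if (abs(cm[hi, lo]) > threshold) keep[lo] <- FALSE
    }
  }
  nms[keep]
}

round_half_up <- function(x) floor(x + 0.5)

#' Candidate focal radii from daily movements
#'
#' The candidate spatial scales are the averages, over individuals, of each
#' individual's minimum, mean and maximum daily step distance, rounded to the
#' nearest metre (half up). For the summer season an extra radius equal to
#' half the (rounded) maximum radius is appended, reflecting the wide range
#' of summer movements. Individuals contributing no steps are excluded with
#' a warning.
#'
#' @param steps `data.frame` with `individual_id` and `distance` (m), e.g.
#'   from [step_distances()].
#' @param season `"nest"`, `"brood"` or `"summer"`.
#' @return List: `variable = NULL` placeholder-free `radii` (increasing
#'   integer metres) and `season`.
#' @export
compute_candidate_radii <- function(steps, season = c("brood", "nest", "summer")) {
  season <- match.arg(season)
  sp <- split(steps$distance, steps$individual_id)
  empty <- names(sp)[vapply(sp, length, 1L) == 0]
  if (length(empty)) {
    warning("excluding individuals with no steps: ", paste(empty, collapse = ", "))
    sp <- sp[vapply(sp, length, 1L) > 0]
  }
  if (!length(sp)) stop("no individuals with step distances")
  per <- vapply(sp, function(d) c(min(d), mean(d), max(d)), numeric(3))
  radii <- round_half_up(rowMeans(per))
  if (season == "summer") radii <- c(radii, round_half_up(radii[3] / 2))
  radii <- sort(unique(unname(radii)))
  list(radii = radii, season = season)
}
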