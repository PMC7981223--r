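#' Georeferenced raster grid
#'
#' Minimal container for a single-band raster in a projected (metric)
#' coordinate system: a numeric matrix of cell values plus an origin, a square
#' cell size and a nodata convention. Rows run south to north (row 1 is the
#' southernmost row), columns west to east; cell (r, c) is centred at
#' `(xmin + (c - 0.5) * cellsize, ymin + (r - 0.5) * cellsize)`.
#'
#' @param values numeric matrix of cell values; `NA` marks nodata.
#' @param xmin,ymin coordinates (m) of the lower-left corner of the grid.
#' @param cellsize cell edge length in metres; must be positive.
#'
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, cellsize = 30) {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) < 1L || ncol(values) < 1L)
    stop("`values` must be a non-empty numeric matrix")
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("`cellsize` must be a single positive number")
  structure(
    list(values = values, xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         cellsize = as.numeric(cellsize)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d rows x %d cols, cell %g m\n",
              nrow(v), ncol(v), x$cellsize))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xmin, x$xmin + ncol(v) * x$cellsize,
              x$ymin, x$ymin + nrow(v) * x$cellsize))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values: [%g, %g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

grid_extent <- function(g) {
  c(xmin = g$xmin, xmax = g$xmin + ncol(g$values) * g$cellsize,
    ymin = g$ymin, ymax = g$ymin + nrow(g$values) * g$cellsize)
}

#' Coordinates of every cell centre
#'
#' @param g a [raster_grid()].
#' @return A two-column matrix (x, y) in row-major order matching
#'   `as.vector(g$values)` (column-major over the value matrix).
#' @export
grid_centers <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  xs <- g$xmin + (seq_len(nc) - 0.5) * g$cellsize
  ys <- g$ymin + (seq_len(nr) - 0.5) * g$cellsize
  cbind(x = rep(xs, each = nr), y = rep(ys, times = nc))
}

stopifnot_same_geometry <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      !isTRUE(all.equal(c(a$xmin, a$ymin, a$cellsize),
                        c(b$xmin, b$ymin, b$cellsize))))
    stop("raster grids are not aligned (differing extent or cell size)")
  invisible(TRUE)
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$cellsize),
                     c(b$xmin, b$ymin, b$cellsize)))
}

#' Extract raster values at point locations
#'
#' Returns the value of the cell containing each point (no interpolation).
#' Points outside the grid return `NA`.
#'
#' @param g a [raster_grid()].
#' @param xy two-column matrix or data frame of point coordinates (m).
#' @return Numeric vector of cell values, one per point.
#' @export
raster_extract <- function(g, xy) {
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  col <- floor((xy[, 1] - g$xmin) / g$cellsize) + 1L
  row <- floor((xy[, 2] - g$ymin) / g$cellsize) + 1L
  nr <- nrow(g$values); nc <- ncol(g$values)
  ok <- col >= 1L & col <= nc & row >= 1L & row <= nr
  out <- rep(NA_real_, nrow(xy))
  out[ok] <- g$values[cbind(row[ok], col[ok])]
  out
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange format (`.asc`): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of values from north to south. Values round-trip at full double
#' precision.
#'
#' @param g a [raster_grid()].
#' @param path file path.
#' @param nodata value written in place of `NA` cells.
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   returns a [raster_grid()].
#' @export
write_ascii_grid <- function(g, path, nodata = -9999) {
  v <- g$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  # ASCII grids store the northernmost row first
  for (r in rev(seq_len(nrow(v)))) {
    row <- v[r, ]
    row[is.na(row)] <- nodata
    writeLines(paste(formatC(row, format = "g", digits = 17), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  vals <- lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  m[m == hdr$nodata_value] <- NA
  raster_grid(m[rev(seq_len(nrow(m))), , drop = FALSE],
              xmin = hdr$xllcorner, ymin = hdr$yllcorner,
              cellsize = hdr$cellsize)
}

#' Write vector features as GeoJSON
#'
#' @param features list with any of `roads`, `streams` (lists of two-column
#'   coordinate matrices, one per polyline), `mesic_centers`, `release_sites`
#'   (two-column point matrices), or a polygon matrix under `boundary`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(features, path) {
  feats <- list()
  add <- function(geom, props) {
    feats[[length(feats) + 1L]] <<- list(
      type = "Feature", properties = props, geometry = geom)
  }
  for (nm in intersect(c("roads", "streams"), names(features))) {
    for (i in seq_along(features[[nm]])) {
      m <- unname(as.matrix(features[[nm]][[i]]))
      add(list(type = "LineString", coordinates = m),
          list(layer = nm, id = i))
    }
  }
  for (nm in intersect(c("mesic_centers", "release_sites"), names(features))) {
    pts <- as.matrix(features[[nm]])
    for (i in seq_len(nrow(pts)))
      add(list(type = "Point", coordinates = unname(pts[i, 1:2])),
          list(layer = nm, id = i))
  }
  if (!is.null(features$boundary)) {
    m <- unname(as.matrix(features$boundary))
    if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
    add(list(type = "Polygon", coordinates = list(m)),
        list(layer = "boundary", id = 1L))
  }
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
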