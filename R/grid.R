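#' Regular lon/lat grid specification
#'
#' Defines a regular WGS84 longitude/latitude raster with cell-center
#' registration and half-open cell ownership `[edge, edge + res)`. The default
#' box covers Europe (10°W-40°E, 35-70°N) at 0.25°.
#'
#' @param lon_min,lon_max,lat_min,lat_max Grid edges in degrees.
#' @param res Cell size in degrees.
#' @return An object of class `grid_spec` with cell-center coordinate vectors
#'   `lon` (west to east) and `lat` (south to north).
#' @examples
#' g <- grid_spec(res = 1)
#' length(g$lon) * length(g$lat)
#' @export
grid_spec <- function(lon_min = -10, lon_max = 40, lat_min = 35, lat_max = 70,
                      res = 0.25) {
  if (!is.numeric(res) || length(res) != 1 || res <= 0)
    stop("invalid grid: `res` must be a single positive number", call. = FALSE)
  if (lon_min >= lon_max || lat_min >= lat_max)
    stop("invalid grid: min edges must be below max edges", call. = FALSE)
  ncol <- (lon_max - lon_min) / res
  nrow <- (lat_max - lat_min) / res
  if (abs(ncol - round(ncol)) > 1e-8 || abs(nrow - round(nrow)) > 1e-8)
    stop("invalid grid: extent is not an integer multiple of `res`",
         call. = FALSE)
  ncol <- as.integer(round(ncol)); nrow <- as.integer(round(nrow))
  structure(
    list(lon_min = lon_min, lon_max = lon_max,
         lat_min = lat_min, lat_max = lat_max,
         res = res, ncol = ncol, nrow = nrow,
         lon = lon_min + res * (seq_len(ncol) - 0.5),
         lat = lat_min + res * (seq_len(nrow) - 0.5)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %g..%g E x %g..%g N @ %g deg (%d x %d cells)\n",
              x$lon_min, x$lon_max, x$lat_min, x$lat_max,
              x$res, x$ncol, x$nrow))
  invisible(x)
}

#' Monthly climate grid container
#'
#' Holds 12 monthly mean temperature layers (and optionally monthly maxima)
#' on a [grid_spec()]. Layers are stored as an array with dimensions
#' `(lat, lon, month)`; latitude rows run south to north.
#'
#' @param grid A [grid_spec()].
#' @param tmean Numeric array `(nrow, ncol, 12)` of monthly mean temperature,
#'   degrees C.
#' @param tmax Optional array of monthly maximum temperature, same shape.
#' @param year Optional calendar year the grid represents (NULL for a
#'   climatology).
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(grid, tmean, tmax = NULL, year = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  expect_dim <- c(grid$nrow, grid$ncol, 12L)
  if (!identical(dim(tmean), expect_dim))
    stop("tmean must have dim (nlat, nlon, 12)", call. = FALSE)
  if (!is.null(tmax) && !identical(dim(tmax), expect_dim))
    stop("tmax must have dim (nlat, nlon, 12)", call. = FALSE)
  structure(list(grid = grid, tmean = tmean, tmax = tmax, year = year),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %s%d x %d cells, 12 months%s\n",
              if (is.null(x$year)) "climatology, " else sprintf("year %d, ", x$year),
              x$grid$nrow, x$grid$ncol,
              if (is.null(x$tmax)) "" else " (+tmax)"))
  invisible(x)
}

# Map lon/lat points to (row, col) indices under half-open cell ownership.
# Points outside the grid get NA.
cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$lon_min) / grid$res) + 1
  row <- floor((lat - grid$lat_min) / grid$res) + 1
  bad <- col < 1 | col > grid$ncol | row < 1 | row > grid$nrow
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}
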