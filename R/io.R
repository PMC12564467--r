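# Shared I/O: Esri ASCII grid rasters, GeoJSON vector layers, and flat
# key-value pipeline configuration files.

#' Write a raster matrix as an Esri ASCII grid
#'
#' Rows are written north to south, as the format requires; values are
#' written with full double precision so a write/read cycle is lossless.
#'
#' @param values Numeric matrix `(nlat, nlon)`, latitude rows south to north
#'   (the in-memory convention).
#' @param grid The [grid_spec()] the raster lives on.
#' @param path Output path (conventionally `.asc`).
#' @param nodata NODATA sentinel; `NA` cells are written as this value.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  stopifnot(identical(dim(values), c(grid$nrow, grid$ncol)))
  header <- c(
    sprintf("ncols %d", grid$ncol),
    sprintf("nrows %d", grid$nrow),
    sprintf("xllcorner %.10g", grid$lon_min),
    sprintf("yllcorner %.10g", grid$lat_min),
    sprintf("cellsize %.10g", grid$res),
    sprintf("NODATA_value %.10g", nodata))
  v <- values
  v[is.na(v)] <- nodata
  body <- vapply(rev(seq_len(grid$nrow)), function(r)
    paste(sprintf("%.17g", v[r, ]), collapse = " "), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an Esri ASCII grid
#'
#' @param path Path to a `.asc` file.
#' @return A list with `values` (matrix, latitude rows south to north, NODATA
#'   as `NA`), `grid` (a [grid_spec()]) and `nodata`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2 || tolower(parts[1]) != keys[i] ||
        is.na(suppressWarnings(as.numeric(parts[2]))))
      stop(sprintf("malformed ASCII grid header at line %d: '%s'", i,
                   lines[i]), call. = FALSE)
    hdr[[keys[i]]] <- as.numeric(parts[2])
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(lines) < 6 + nr)
    stop(sprintf("ASCII grid truncated: expected %d data rows, found %d",
                 nr, length(lines) - 6), call. = FALSE)
  values <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    row <- suppressWarnings(as.numeric(
      strsplit(trimws(lines[6 + r]), "\\s+")[[1]]))
    if (length(row) != nc || anyNA(row))
      stop(sprintf("malformed ASCII grid data at line %d", 6 + r),
           call. = FALSE)
    values[nr - r + 1, ] <- row  # file rows run north to south
  }
  values[values == hdr$nodata_value] <- NA_real_
  grid <- grid_spec(lon_min = hdr$xllcorner,
                    lon_max = hdr$xllcorner + nc * hdr$cellsize,
                    lat_min = hdr$yllcorner,
                    lat_max = hdr$yllcorner + nr * hdr$cellsize,
                    res = hdr$cellsize)
  list(values = values, grid = grid, nodata = hdr$nodata_value)
}

#' Write a point layer as GeoJSON
#'
#' @param df Data frame with `lon` and `lat` columns; all other columns
#'   become feature properties.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson_points <- function(df, path) {
  props <- setdiff(names(df), c("lon", "lat"))
  feats <- lapply(seq_len(nrow(df)), function(i) {
    p <- lapply(df[i, props, drop = FALSE], function(v)
      if (is.factor(v)) as.character(v) else v)
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$lon[i], df$lat[i])),
         properties = p)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write buffer zones as GeoJSON polygons
#'
#' @param zones A `buffer_zones` object from [buffer_zones()].
#' @param path Output path.
#' @param metadata Optional named list recorded as foreign members of the
#'   collection (e.g. the radius rule used).
#' @return `path`, invisibly.
#' @export
write_geojson_polygons <- function(zones, path, metadata = NULL) {
  feats <- lapply(zones, function(z) {
    ring <- lapply(seq_len(nrow(z$ring)), function(i)
      c(z$ring[i, "lon"], z$ring[i, "lat"]))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(country = z$country, class = z$class,
                           radius_km = z$radius_km, horizon = z$horizon))
  })
  doc <- list(type = "FeatureCollection", features = feats)
  if (!is.null(metadata)) doc$metadata <- metadata
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON point layer back into a data frame
#'
#' @param path Path written by [write_geojson_points()].
#' @return Data frame with `lon`, `lat` and the property columns.
#' @export
read_geojson_points <- function(path) {
  doc <- jsonlite::read_json(path)
  rows <- lapply(doc$features, function(f) {
    c(list(lon = f$geometry$coordinates[[1]],
           lat = f$geometry$coordinates[[2]]),
      f$properties)
  })
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Write / read a pipeline configuration
#'
#' Configurations are flat key-value YAML documents; a write/read cycle
#' returns an identical list.
#'
#' @param config A [pipeline_config()] (any flat named list of scalars and
#'   numeric vectors).
#' @param path File path.
#' @return `path` invisibly for the writer; the configuration list for the
#'   reader.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}
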