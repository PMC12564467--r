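# Synthetic gridded climate with the statistical structure the analysis
# assumes: latitude-dominated climatology, a July-peaking seasonal cycle,
# a decadal warming trend and spatially smooth, seeded anomaly fields.

#' Parameters of the synthetic European climatology
#'
#' @param sea_level_july_temp July mean at the 45°N reference latitude, °C.
#' @param lapse_per_lat Cooling per degree of latitude northwards, °C/degree.
#' @param seasonal_amplitude Half-range of the annual temperature cycle, °C.
#' @param noise_sd Cell-level Gaussian standard deviation, °C. Zero gives a
#'   fully deterministic surface.
#' @param trend_per_year Linear warming trend over 1991-2024, °C/yr, centred
#'   on the 1991-2020 reference midpoint (2005.5) so the reference-period
#'   mean equals the climatology.
#' @param seed Integer RNG seed; identical seed and parameters reproduce
#'   bit-identical output.
#' @return An object of class `climatology_params`.
#' @export
climatology_params <- function(sea_level_july_temp = 22.0,
                               lapse_per_lat = 0.7,
                               seasonal_amplitude = 10.0,
                               noise_sd = 0.5,
                               trend_per_year = 0.04,
                               seed = 42L) {
  if (lapse_per_lat < 0 || seasonal_amplitude < 0 || noise_sd < 0)
    stop("lapse_per_lat, seasonal_amplitude and noise_sd must be >= 0",
         call. = FALSE)
  structure(list(sea_level_july_temp = sea_level_july_temp,
                 lapse_per_lat = lapse_per_lat,
                 seasonal_amplitude = seasonal_amplitude,
                 noise_sd = noise_sd,
                 trend_per_year = trend_per_year,
                 seed = as.integer(seed)),
            class = "climatology_params")
}

#' Generate a synthetic monthly climatology
#'
#' Monthly mean temperature is
#' `T(lat, m) = a - lapse * lat + A * cos(2*pi*(m - 7)/12) + eps`, with the
#' intercept `a` fixed so that July at 45°N equals `sea_level_july_temp` and
#' `eps ~ N(0, noise_sd^2)` per cell and month (seeded). With zero noise,
#' July is the warmest month everywhere and temperature decreases strictly
#' with latitude.
#'
#' @param grid A [grid_spec()].
#' @param params A [climatology_params()].
#' @return A [climate_grid()] climatology (year = NULL).
#' @examples
#' cl <- generate_climatology(grid_spec(res = 5),
#'                            climatology_params(noise_sd = 0))
#' @export
generate_climatology <- function(grid, params = climatology_params()) {
  stopifnot(inherits(grid, "grid_spec"), inherits(params, "climatology_params"))
  a <- params$sea_level_july_temp + params$lapse_per_lat * 45 -
    params$seasonal_amplitude
  tmean <- array(0, dim = c(grid$nrow, grid$ncol, 12L))
  for (m in 1:12) {
    seasonal <- params$seasonal_amplitude * cos(2 * pi * (m - 7) / 12)
    tmean[, , m] <- matrix(a - params$lapse_per_lat * grid$lat + seasonal,
                           nrow = grid$nrow, ncol = grid$ncol)
  }
  if (params$noise_sd > 0) {
    tmean <- tmean + withr::with_seed(
      params$seed,
      array(stats::rnorm(length(tmean), sd = params$noise_sd), dim = dim(tmean)))
  }
  climate_grid(grid, tmean)
}

# Smooth low-frequency anomaly surface: a seeded 6-term trigonometric basis
# over normalised grid coordinates, scaled by `sd`. Guarantees that coherent
# "regions of stronger warming" exist by construction.
smooth_anomaly_field <- function(grid, sd, seed) {
  if (sd == 0) return(matrix(0, grid$nrow, grid$ncol))
  u <- (grid$lon - grid$lon_min) / (grid$lon_max - grid$lon_min)
  v <- (grid$lat - grid$lat_min) / (grid$lat_max - grid$lat_min)
  co <- withr::with_seed(seed, stats::rnorm(6))
  U <- matrix(u, grid$nrow, grid$ncol, byrow = TRUE)
  V <- matrix(v, grid$nrow, grid$ncol)
  sd * (co[1] * sin(pi * U) + co[2] * cos(pi * V) +
          co[3] * sin(pi * U) * cos(pi * V) +
          co[4] * sin(2 * pi * U) + co[5] * cos(2 * pi * V) +
          co[6] * sin(2 * pi * U) * sin(pi * V)) / sqrt(6)
}

#' Generate an annual series of synthetic monthly grids
#'
#' Each year's grid is the climatology plus a linear trend
#' `trend_per_year * (year - 2005.5)` plus a smooth, seeded annual anomaly
#' field (shared across the 12 months of that year). Centring the trend on
#' 2005.5 makes the 1991-2020 mean equal the climatology up to anomaly noise.
#' Per-year anomaly seeds are derived from `params$seed` and the year, so a
#' given year's field does not depend on the requested range.
#'
#' @param grid A [grid_spec()].
#' @param params A [climatology_params()].
#' @param years Integer vector of years within 1991-2100.
#' @return A named list of [climate_grid()] objects, one per year.
#' @export
generate_annual_series <- function(grid, params = climatology_params(),
                                   years = 1991:2024) {
  if (length(years) == 0) stop("empty year range", call. = FALSE)
  years <- as.integer(years)
  if (any(years < 1991L | years > 2100L))
    stop("years must lie within 1991-2100", call. = FALSE)
  clim <- generate_climatology(grid, params)
  out <- lapply(years, function(y) {
    offset <- params$trend_per_year * (y - 2005.5)
    anom <- smooth_anomaly_field(grid, params$noise_sd,
                                 child_seed(params$seed, y))
    tmean <- clim$tmean + offset
    for (m in 1:12) tmean[, , m] <- tmean[, , m] + anom
    climate_grid(grid, tmean, year = y)
  })
  names(out) <- years
  out
}

PRESENCE_STATUSES <- c("absent", "widespread", "restricted",
                       "few_occurrences", "eradicated", "transient")

#' Generate a synthetic presence history radiating from an origin
#'
#' Emulates the documented invasion pattern: first detection near Belgrade,
#' Serbia (1992), then outward expansion, with first-detection year
#' increasing with great-circle distance from the origin. Status codes follow
#' the standard six-value vocabulary used by plant-protection databases
#' (absent, widespread, restricted, few_occurrences, eradicated, transient).
#'
#' @param origin Numeric `c(lon, lat)` of the first detection.
#' @param years Integer range of the history (first year = detection year at
#'   the origin).
#' @param spread_rate Radial expansion rate in degrees of great-circle arc
#'   per year; 0 keeps the infestation at the origin only.
#' @param countries Optional data frame with columns `country`, `lon`, `lat`
#'   giving the points to classify; defaults to the packaged country
#'   centroids (Moldova excluded, matching the source distribution data).
#' @param seed Integer seed for the status jitter.
#' @return A list with `records` (data frame of country/year/status rows) and
#'   `points` (data frame country/lon/lat/first_year).
#' @export
generate_presence_history <- function(origin = c(20.5, 44.8),
                                      years = 1992:2024,
                                      spread_rate = 0.35,
                                      countries = NULL,
                                      seed = 42L) {
  if (spread_rate < 0) stop("spread_rate must be >= 0", call. = FALSE)
  if (length(years) == 0) stop("empty year range", call. = FALSE)
  if (is.null(countries)) {
    countries <- load_centroid_fixture()[, c("country", "lon", "lat")]
    countries <- countries[countries$country != "Moldova", ]
  }
  y0 <- min(years)
  dist_deg <- geosphere::distHaversine(
    cbind(countries$lon, countries$lat), origin) / 111194.9
  origin_country <- which.min(dist_deg)
  first_year <- if (spread_rate == 0) {
    rep(NA_integer_, length(dist_deg))
  } else {
    fy <- y0 + ceiling(dist_deg / spread_rate)
    ifelse(fy <= max(years), as.integer(fy), NA_integer_)
  }
  first_year[origin_country] <- y0  # detection at the origin in the first year
  points <- data.frame(country = countries$country,
                       lon = countries$lon, lat = countries$lat,
                       first_year = first_year,
                       stringsAsFactors = FALSE)
  recs <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(points)), function(i) {
      fy <- points$first_year[i]
      status <- vapply(years, function(y) {
        if (is.na(fy) || y < fy) return("absent")
        age <- y - fy
        if (age == 0) "few_occurrences"
        else if (age < 5 + sample(0:2, 1)) "restricted"
        else "widespread"
      }, character(1))
      data.frame(country = points$country[i], year = years, status = status,
                 stringsAsFactors = FALSE)
    }))
  })
  recs$status <- factor(recs$status, levels = PRESENCE_STATUSES)
  list(records = recs, points = points)
}
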