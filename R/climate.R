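# Warming schedule, temperature anomalies (DAT) against the 1991-2020
# reference, warm-season statistics and growing-degree-day accumulation.

#' Linear continental warming schedule
#'
#' An affine rule for the projected mean temperature increase over Europe
#' relative to the pre-industrial baseline: anchored at +1.4 °C in 2024 and
#' rising 0.2 °C per 5 years, which reproduces every tabulated 5-year value
#' through +2.6 °C at 2054 and extrapolates linearly beyond.
#'
#' @param anchor_year Year at which the schedule is anchored (2024).
#' @param anchor_delta Temperature increase at the anchor year, °C.
#' @param step_per_5yr Increase per 5 years, °C.
#' @return An object of class `warming_schedule`.
#' @export
warming_schedule <- function(anchor_year = 2024L, anchor_delta = 1.4,
                             step_per_5yr = 0.2) {
  structure(list(anchor_year = as.integer(anchor_year),
                 anchor_delta = anchor_delta,
                 step_per_5yr = step_per_5yr),
            class = "warming_schedule")
}

#' Evaluate the warming schedule at a projection year
#'
#' @param year Integer year(s), at or after the schedule's anchor year.
#'   Historical years are handled by anomalies, not the schedule.
#' @param schedule A [warming_schedule()].
#' @return Temperature increase in °C (vectorised over `year`).
#' @examples
#' warming_delta(c(2024, 2034, 2054))
#' @export
warming_delta <- function(year, schedule = warming_schedule()) {
  if (any(year < schedule$anchor_year))
    stop("year precedes the schedule anchor (", schedule$anchor_year,
         "); use anomaly_map() for historical years", call. = FALSE)
  schedule$anchor_delta + (schedule$step_per_5yr / 5) *
    (year - schedule$anchor_year)
}

#' Shift every monthly layer of a grid by a constant
#'
#' @param grid A [climate_grid()].
#' @param delta Finite temperature shift in °C, applied to every cell and
#'   month (and to `tmax` if present).
#' @return The shifted [climate_grid()].
#' @export
apply_warming <- function(grid, delta) {
  stopifnot(inherits(grid, "climate_grid"), is.finite(delta))
  grid$tmean <- grid$tmean + delta
  if (!is.null(grid$tmax)) grid$tmax <- grid$tmax + delta
  grid
}

#' The 1991-2020 reference period
#' @param start,end First and last year, inclusive.
#' @return A list with `start` and `end`.
#' @export
reference_period <- function(start = 1991L, end = 2020L) {
  if (start > end) stop("reference start must not exceed end", call. = FALSE)
  list(start = as.integer(start), end = as.integer(end))
}

#' The six cumulative anomaly periods P1-P6
#'
#' @return A data frame with columns `label`, `start`, `end` for the six
#'   cumulative intervals 1991-1992, 1992-2002, 1992-2012, 1992-2020,
#'   1992-2022 and 1992-2024.
#' @export
period_definitions <- function() {
  data.frame(label = paste0("P", 1:6),
             start = c(1991L, 1992L, 1992L, 1992L, 1992L, 1992L),
             end = c(1992L, 2002L, 2012L, 2020L, 2022L, 2024L),
             stringsAsFactors = FALSE)
}

#' Warm-season window and activity threshold
#'
#' April-September growing season with the 15 °C mean-temperature threshold
#' used for the adult-activity overlap analysis.
#'
#' @param start_month,end_month Window bounds, 1-based months.
#' @param activity_mean_threshold Mean temperature threshold, °C.
#' @return A list of the three fields.
#' @export
season_window <- function(start_month = 4L, end_month = 9L,
                          activity_mean_threshold = 15) {
  if (!(start_month >= 1 && start_month <= end_month && end_month <= 12))
    stop("need 1 <= start_month <= end_month <= 12", call. = FALSE)
  list(start_month = as.integer(start_month),
       end_month = as.integer(end_month),
       activity_mean_threshold = activity_mean_threshold)
}

# Per-cell annual mean of a climate_grid. Default is the unweighted mean of
# the 12 monthly means; `day_weighted` weights by month length instead.
annual_mean <- function(grid, day_weighted = FALSE) {
  stopifnot(inherits(grid, "climate_grid"))
  if (day_weighted) {
    w <- DAYS_IN_MONTH / sum(DAYS_IN_MONTH)
    out <- matrix(0, grid$grid$nrow, grid$grid$ncol)
    for (m in 1:12) out <- out + w[m] * grid$tmean[, , m]
    out
  } else {
    apply(grid$tmean, c(1, 2), mean)
  }
}

#' Temperature anomaly (DAT) raster for a period against a reference
#'
#' Per cell: the mean annual temperature over the period years minus the mean
#' over the reference years (Deviation from Average Temperatures, °C).
#'
#' @param series Named list of [climate_grid()] objects (names = years), as
#'   produced by [generate_annual_series()].
#' @param period A list/row with `start` and `end` years (e.g. one row of
#'   [period_definitions()]).
#' @param ref A [reference_period()].
#' @param day_weighted Use day-weighted annual means (default unweighted).
#' @return A numeric matrix `(nlat, nlon)` of anomalies in °C.
#' @export
anomaly_map <- function(series, period, ref = reference_period(),
                        day_weighted = FALSE) {
  have <- as.integer(names(series))
  py <- period$start:period$end
  ry <- ref$start:ref$end
  miss <- setdiff(c(py, ry), have)
  if (length(miss))
    stop("series does not cover years: ", paste(miss, collapse = ", "),
         call. = FALSE)
  mean_over <- function(yrs) {
    acc <- 0
    for (y in yrs) acc <- acc + annual_mean(series[[as.character(y)]],
                                            day_weighted)
    acc / length(yrs)
  }
  mean_over(py) - mean_over(ry)
}

#' Growing degree days from monthly means
#'
#' Accumulated heat above a base temperature,
#' `sum_m max(0, T_m - base) * days_in_month(m)` on a non-leap calendar
#' (monthly-resolution approximation; no daily downscaling).
#'
#' @param x A 12-vector of monthly mean temperatures (°C) or a
#'   [climate_grid()].
#' @param base Base temperature, °C (10 °C for maize maturity).
#' @return A scalar for a vector input, or a `(nlat, nlon)` matrix of GDD for
#'   a grid.
#' @examples
#' gdd(c(0, 0, 0, 20, 20, 20, 20, 20, 20, 0, 0, 0), base = 10) # 1830
#' @export
gdd <- function(x, base = 10) {
  stopifnot(is.finite(base))
  if (inherits(x, "climate_grid")) {
    out <- matrix(0, x$grid$nrow, x$grid$ncol)
    for (m in 1:12)
      out <- out + pmax(0, x$tmean[, , m] - base) * DAYS_IN_MONTH[m]
    out
  } else {
    if (length(x) != 12) stop("need 12 monthly values", call. = FALSE)
    sum(pmax(0, x - base) * DAYS_IN_MONTH)
  }
}

#' Warm-season mean temperature raster
#'
#' @param grid A [climate_grid()].
#' @param window A [season_window()] (April-September by default).
#' @return A `(nlat, nlon)` matrix of mean temperature over the window
#'   months, °C.
#' @export
warm_season_mean <- function(grid, window = season_window()) {
  stopifnot(inherits(grid, "climate_grid"))
  months <- window$start_month:window$end_month
  apply(grid$tmean[, , months, drop = FALSE], c(1, 2), mean)
}

#' Fraction of presence points lying in warmed cells
#'
#' Overlays presence points on a DAT raster and returns the fraction whose
#' cell anomaly is at or above the threshold. Points outside the grid are
#' dropped from the denominator with a warning.
#'
#' @param points Data frame with `lon` and `lat` columns.
#' @param dat Anomaly matrix from [anomaly_map()].
#' @param grid The [grid_spec()] the raster lives on.
#' @param threshold Anomaly threshold in °C.
#' @return A fraction in `[0, 1]`, or `NA` (with a warning) if no usable
#'   points remain.
#' @export
presence_anomaly_overlap <- function(points, dat, grid, threshold) {
  idx <- cell_index(grid, points$lon, points$lat)
  out_of_grid <- is.na(idx$row)
  if (any(out_of_grid))
    warning(sum(out_of_grid), " point(s) outside the grid were excluded")
  idx <- idx[!out_of_grid, , drop = FALSE]
  if (nrow(idx) == 0) {
    warning("no presence points inside the grid; overlap undefined")
    return(NA_real_)
  }
  vals <- dat[cbind(idx$row, idx$col)]
  mean(vals >= threshold)
}
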