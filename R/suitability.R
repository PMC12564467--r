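# Thermal-envelope suitability: threshold + persistence classification of
# grid cells for beetle activity/establishment and for maize cultivation.

#' Thermal thresholds for the beetle
#'
#' Adult activity requires a monthly mean of at least 12.5 °C in temperate
#' zones; establishment in colder climates requires at least 9 °C. Either
#' threshold must hold for at least two consecutive growing-season months
#' (April-September). The optimal development range (18-32 °C) is carried as
#' metadata.
#'
#' @param activity_min,establishment_min Monthly-mean thresholds, °C.
#' @param optimal_lo,optimal_hi Optimal development range, °C.
#' @param persistence_months Required consecutive months at/above threshold.
#' @param window A [season_window()].
#' @return An object of class `pest_thresholds`.
#' @export
pest_thresholds <- function(activity_min = 12.5, establishment_min = 9,
                            optimal_lo = 18, optimal_hi = 32,
                            persistence_months = 2L,
                            window = season_window()) {
  if (!(establishment_min < activity_min && activity_min < optimal_lo &&
          optimal_lo < optimal_hi))
    stop("need establishment_min < activity_min < optimal_lo < optimal_hi",
         call. = FALSE)
  if (persistence_months < 1) stop("persistence_months must be >= 1",
                                   call. = FALSE)
  structure(list(activity_min = activity_min,
                 establishment_min = establishment_min,
                 optimal_lo = optimal_lo, optimal_hi = optimal_hi,
                 persistence_months = as.integer(persistence_months),
                 window = window),
            class = "pest_thresholds")
}

#' Thermal thresholds for maize cultivation
#'
#' @param germination_min Minimum monthly mean (soil proxied by air), °C.
#' @param optimal_lo,optimal_hi Optimal growth range, °C.
#' @param heat_stress_max Monthly maximum above which heat stress is assumed,
#'   °C.
#' @param gdd_lo,gdd_hi Required heat-sum range for maturity, degree-days.
#' @param gdd_base GDD base temperature, °C.
#' @param tmax_offset When a grid carries no monthly maxima, they are proxied
#'   as mean + this offset, °C.
#' @return An object of class `maize_thresholds`.
#' @export
maize_thresholds <- function(germination_min = 10, optimal_lo = 24,
                             optimal_hi = 30, heat_stress_max = 35,
                             gdd_lo = 1000, gdd_hi = 1400, gdd_base = 10,
                             tmax_offset = 6) {
  if (!(germination_min < optimal_lo && optimal_lo < optimal_hi &&
          optimal_hi < heat_stress_max))
    stop("need germination_min < optimal_lo < optimal_hi < heat_stress_max",
         call. = FALSE)
  if (gdd_lo > gdd_hi) stop("gdd_lo must not exceed gdd_hi", call. = FALSE)
  structure(list(germination_min = germination_min, optimal_lo = optimal_lo,
                 optimal_hi = optimal_hi, heat_stress_max = heat_stress_max,
                 gdd_lo = gdd_lo, gdd_hi = gdd_hi, gdd_base = gdd_base,
                 tmax_offset = tmax_offset),
            class = "maize_thresholds")
}

#' Persistence rule: k consecutive window months at or above a threshold
#'
#' TRUE iff some run of at least `k` consecutive months inside the seasonal
#' window all have means at or above `threshold` (inclusive comparison).
#' Consecutive means adjacent calendar months within the window.
#'
#' @param monthly A 12-vector of monthly means, °C.
#' @param threshold Threshold, °C.
#' @param k Required run length.
#' @param window A [season_window()].
#' @return Logical scalar.
#' @examples
#' persistent_exceedance(c(0,0,0, 11,12,13,14,13,10, 0,0,0), 12.5, 2)
#' @export
persistent_exceedance <- function(monthly, threshold, k = 2L,
                                  window = season_window()) {
  if (length(monthly) != 12) stop("need 12 monthly values", call. = FALSE)
  months <- window$start_month:window$end_month
  if (k > length(months))
    stop("k exceeds the window length", call. = FALSE)
  hit <- monthly[months] >= threshold
  r <- rle(hit)
  any(r$values & r$lengths >= k)
}

# Vectorised run-length check on an array (nlat, nlon, nwin): TRUE where some
# k-run of window layers is all TRUE. k is small (2), so a sliding all-of-k
# over window positions is cheap.
mask_persistent <- function(grid, threshold, k, window) {
  months <- window$start_month:window$end_month
  nw <- length(months)
  if (k > nw) stop("k exceeds the window length", call. = FALSE)
  hit <- grid$tmean[, , months, drop = FALSE] >= threshold
  out <- matrix(FALSE, dim(hit)[1], dim(hit)[2])
  for (s in 1:(nw - k + 1)) {
    run <- hit[, , s]
    if (k > 1) for (j in 1:(k - 1)) run <- run & hit[, , s + j]
    out <- out | run
  }
  out
}

new_suitability_mask <- function(mask, rule) {
  structure(list(mask = mask, rule = rule), class = "suitability_mask")
}

#' @export
print.suitability_mask <- function(x, ...) {
  cat(sprintf("<suitability_mask> %s: %d / %d cells suitable\n",
              x$rule$name %||% "rule", sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Beetle activity and establishment suitability masks
#'
#' Applies the persistence rule per cell at the 12.5 °C (activity) and 9 °C
#' (establishment) thresholds. Because the activity threshold is the higher
#' of the two, the activity mask is always nested inside the establishment
#' mask.
#'
#' @param grid A [climate_grid()].
#' @param thresholds A [pest_thresholds()].
#' @return A list with `activity` and `establishment`, each a
#'   `suitability_mask` (logical matrix plus rule metadata).
#' @export
pest_suitability_mask <- function(grid, thresholds = pest_thresholds()) {
  stopifnot(inherits(grid, "climate_grid"))
  k <- thresholds$persistence_months
  w <- thresholds$window
  list(
    activity = new_suitability_mask(
      mask_persistent(grid, thresholds$activity_min, k, w),
      list(name = "activity", threshold = thresholds$activity_min,
           persistence_months = k, window = c(w$start_month, w$end_month))),
    establishment = new_suitability_mask(
      mask_persistent(grid, thresholds$establishment_min, k, w),
      list(name = "establishment", threshold = thresholds$establishment_min,
           persistence_months = k, window = c(w$start_month, w$end_month))))
}

#' Maize cultivation suitability mask
#'
#' A cell is suitable iff (i) its GDD at the base temperature reaches the
#' lower maturity bound, (ii) at least one window month has a mean at or
#' above the germination minimum, and (iii) no window month's maximum
#' exceeds the heat-stress limit. Monthly maxima are taken from the grid's
#' `tmax` layers, or proxied as mean + `tmax_offset` when absent.
#'
#' @param grid A [climate_grid()].
#' @param thresholds A [maize_thresholds()].
#' @param window A [season_window()].
#' @return A `suitability_mask`.
#' @export
maize_suitability_mask <- function(grid, thresholds = maize_thresholds(),
                                   window = season_window()) {
  stopifnot(inherits(grid, "climate_grid"))
  months <- window$start_month:window$end_month
  heat <- gdd(grid, base = thresholds$gdd_base) >= thresholds$gdd_lo
  germ <- apply(grid$tmean[, , months, drop = FALSE] >=
                  thresholds$germination_min, c(1, 2), any)
  tmax <- grid$tmax %||% (grid$tmean + thresholds$tmax_offset)
  stress <- apply(tmax[, , months, drop = FALSE] >
                    thresholds$heat_stress_max, c(1, 2), any)
  new_suitability_mask(
    heat & germ & !stress,
    list(name = "maize", gdd_lo = thresholds$gdd_lo,
         gdd_base = thresholds$gdd_base,
         germination_min = thresholds$germination_min,
         heat_stress_max = thresholds$heat_stress_max,
         tmax_proxied = is.null(grid$tmax)))
}

# Even-odd ray-cast point-in-polygon for cell centres; polygon is a data
# frame/matrix of lon,lat vertices (closed implicitly).
point_in_polygon <- function(lon, lat, poly_lon, poly_lat) {
  n <- length(poly_lon)
  inside <- rep(FALSE, length(lon))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((poly_lat[i] > lat) != (poly_lat[j] > lat)) &
      (lon < (poly_lon[j] - poly_lon[i]) * (lat - poly_lat[i]) /
         (poly_lat[j] - poly_lat[i]) + poly_lon[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Area-weighted suitable fraction of a region
#'
#' Fraction of a region's grid cells that are suitable, weighting each cell
#' by `cos(latitude)` so that cell areas on the sphere are respected.
#'
#' @param mask A `suitability_mask` (or plain logical matrix).
#' @param grid The [grid_spec()] the mask lives on.
#' @param region Optional polygon (data frame with `lon`, `lat` vertex
#'   columns); `NULL` uses the whole grid.
#' @return Fraction in `[0, 1]`.
#' @export
suitable_fraction <- function(mask, grid, region = NULL) {
  m <- if (inherits(mask, "suitability_mask")) mask$mask else mask
  w <- matrix(cos(grid$lat * pi / 180), grid$nrow, grid$ncol)
  if (!is.null(region)) {
    lon <- matrix(grid$lon, grid$nrow, grid$ncol, byrow = TRUE)
    lat <- matrix(grid$lat, grid$nrow, grid$ncol)
    inside <- point_in_polygon(as.vector(lon), as.vector(lat),
                               region$lon, region$lat)
    if (!any(inside)) stop("region polygon does not overlap the grid",
                           call. = FALSE)
    w <- w * matrix(inside, grid$nrow, grid$ncol)
  }
  sum(w * m) / sum(w)
}
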