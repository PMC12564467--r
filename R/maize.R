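# Maize area estimation, cultivation bands and the projected continental
# expansion curve.

#' Final maize area from the last two annual values
#'
#' Averages the last two official annual areas (million ha), rounds half-up
#' to one decimal in million-ha units, and converts to thousand ha. E.g. an
#' average of 2.5 Mha is reported as 2500 k ha.
#'
#' @param two_year_values Numeric vector of two non-negative areas in
#'   million ha.
#' @return Final area in thousand ha.
#' @examples
#' estimate_final_area(c(2.43, 2.52)) # 2500
#' @export
estimate_final_area <- function(two_year_values) {
  if (length(two_year_values) != 2 || any(two_year_values < 0))
    stop("need two non-negative areas in million ha", call. = FALSE)
  round_half_up(mean(two_year_values), 1) * 1000
}

#' Maize cultivation area bands
#'
#' Four bands partitioning the non-negative areas (thousand ha):
#' small `[0, 500)`, moderate `[500, 1000)`, large_medium `[1000, 2000]`,
#' very_large `(2000, Inf)`. Merging the top two recovers the three-band
#' intensive/moderate/weak scheme.
#'
#' @param small_max,moderate_max,large_max Band edges, thousand ha.
#' @return An object of class `area_bands`.
#' @export
area_bands <- function(small_max = 500, moderate_max = 1000,
                       large_max = 2000) {
  stopifnot(0 < small_max, small_max < moderate_max, moderate_max < large_max)
  structure(list(small_max = small_max, moderate_max = moderate_max,
                 large_max = large_max,
                 levels = c("small", "moderate", "large_medium",
                            "very_large")),
            class = "area_bands")
}

#' Band of a maize area
#'
#' @param area_kha Non-negative area(s) in thousand ha.
#' @param bands An [area_bands()].
#' @param merged If TRUE, collapse large_medium and very_large into
#'   `intensive` (the three-band reporting view).
#' @return Factor of band labels.
#' @examples
#' band_of(c(2500, 750, 499.9))
#' @export
band_of <- function(area_kha, bands = area_bands(), merged = FALSE) {
  if (any(area_kha < 0)) stop("area must be >= 0", call. = FALSE)
  lab <- ifelse(area_kha < bands$small_max, "small",
         ifelse(area_kha < bands$moderate_max, "moderate",
         ifelse(area_kha <= bands$large_max, "large_medium", "very_large")))
  if (merged) {
    lab[lab %in% c("large_medium", "very_large")] <- "intensive"
    factor(lab, levels = c("small", "moderate", "intensive"))
  } else {
    factor(lab, levels = bands$levels)
  }
}

#' Continental maize expansion curve
#'
#' Exponential growth anchored at 6000 thousand ha in 2024 with the rate
#' chosen so the curve reaches 20 million ha by 2054
#' (`rate = log(20/6)/30` per year). A linear variant interpolating the same
#' endpoints is available.
#'
#' @param a0 Area at the anchor year, thousand ha.
#' @param rate Continuous growth rate per year.
#' @param anchor_year Anchor year.
#' @param shape `"exponential"` (default) or `"linear"`.
#' @return An object of class `maize_growth_curve`.
#' @export
maize_growth_curve <- function(a0 = 6000, rate = log(20 / 6) / 30,
                               anchor_year = 2024L,
                               shape = c("exponential", "linear")) {
  if (a0 <= 0) stop("a0 must be > 0", call. = FALSE)
  structure(list(a0 = a0, rate = rate, anchor_year = as.integer(anchor_year),
                 shape = match.arg(shape)),
            class = "maize_growth_curve")
}

#' Projected continental maize area at a year
#'
#' @param year Year(s) between 2024 and 2074.
#' @param curve A [maize_growth_curve()].
#' @return Area in thousand ha.
#' @examples
#' project_area(2054) / 1000 # ~20 million ha
#' @export
project_area <- function(year, curve = maize_growth_curve()) {
  if (any(year < curve$anchor_year | year > 2074))
    stop("year must lie within ", curve$anchor_year, "-2074", call. = FALSE)
  t <- year - curve$anchor_year
  if (curve$shape == "exponential") curve$a0 * exp(curve$rate * t)
  else curve$a0 + curve$a0 * (exp(curve$rate * 30) - 1) * t / 30
}
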