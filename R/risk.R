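# Centroid-based country risk classification, calibrated latitude cuts,
# buffer-zone generation and the joint temperature/maize/spread series.

#' Calibrate per-horizon latitude cuts from a risk fixture
#'
#' For each horizon, the high-risk cut is the midpoint between the
#' highest-latitude HR country and the lowest-latitude MR country, and the
#' medium-risk cut the midpoint between the highest-latitude MR and the
#' lowest-latitude LR country. The fixture must be latitude-separable by
#' class; otherwise the violating countries are reported. The calibrated
#' cuts reproduce every fixture row by construction.
#'
#' @param fixture A data frame as returned by [load_centroid_fixture()].
#' @param horizons Integer vector of horizon years with `risk_<h>` columns.
#' @return An object of class `latitude_cuts`: a data frame with columns
#'   `horizon`, `c_hr`, `c_mr`.
#' @examples
#' calibrate_latitude_cuts(load_centroid_fixture())
#' @export
calibrate_latitude_cuts <- function(fixture, horizons = RISK_HORIZONS) {
  rows <- lapply(horizons, function(h) {
    cls <- fixture[[paste0("risk_", h)]]
    for (lv in RISK_LEVELS)
      if (!any(cls == lv))
        stop("horizon ", h, ": no country in class ", lv, call. = FALSE)
    hi <- function(lv) max(fixture$lat[cls == lv])
    lo <- function(lv) min(fixture$lat[cls == lv])
    check_sep <- function(lower, upper) {
      if (hi(lower) >= lo(upper)) {
        bad_lo <- fixture$country[cls == lower & fixture$lat >= lo(upper)]
        bad_up <- fixture$country[cls == upper & fixture$lat <= hi(lower)]
        stop("horizon ", h, ": classes ", lower, "/", upper,
             " not latitude-separable (", paste(bad_lo, collapse = ", "),
             " vs ", paste(bad_up, collapse = ", "), ")", call. = FALSE)
      }
    }
    check_sep("HR", "MR")
    check_sep("MR", "LR")
    data.frame(horizon = h,
               c_hr = (hi("HR") + lo("MR")) / 2,
               c_mr = (hi("MR") + lo("LR")) / 2)
  })
  cuts <- do.call(rbind, rows)
  structure(cuts, class = c("latitude_cuts", "data.frame"))
}

#' Classify a centroid latitude at a horizon
#'
#' HR below or at the high-risk cut, MR between the cuts, LR above the
#' medium-risk cut. Severity is non-increasing in latitude at a fixed
#' horizon, and (with cuts rising over horizons) non-decreasing over time at
#' a fixed latitude.
#'
#' @param lat Centroid latitude(s), degrees N.
#' @param horizon One of the calibrated horizon years.
#' @param cuts A `latitude_cuts` object from [calibrate_latitude_cuts()].
#' @return Ordered factor `LR < MR < HR`.
#' @export
classify_country <- function(lat, horizon, cuts) {
  i <- match(horizon, cuts$horizon)
  if (is.na(i)) stop("unknown horizon ", horizon, "; calibrated horizons: ",
                     paste(cuts$horizon, collapse = ", "), call. = FALSE)
  cls <- ifelse(lat <= cuts$c_hr[i], "HR",
         ifelse(lat <= cuts$c_mr[i], "MR", "LR"))
  factor(cls, levels = RISK_LEVELS, ordered = TRUE)
}

#' Country risk table with agreement report
#'
#' Classifies every fixture country at every calibrated horizon and compares
#' against the fixture's reference classes.
#'
#' @param fixture A risk fixture data frame.
#' @param cuts Calibrated `latitude_cuts`.
#' @return The fixture with added `pred_<h>` columns, plus an `agreement`
#'   attribute (data frame horizon/matches/total).
#' @export
risk_table <- function(fixture, cuts) {
  out <- fixture
  agree <- lapply(cuts$horizon, function(h) {
    pred <- classify_country(fixture$lat, h, cuts)
    out[[paste0("pred_", h)]] <<- pred
    data.frame(horizon = h,
               matches = sum(as.character(pred) ==
                               as.character(fixture[[paste0("risk_", h)]])),
               total = nrow(fixture))
  })
  attr(out, "agreement") <- do.call(rbind, agree)
  out
}

#' Default buffer radius rule
#'
#' Radii in km by class at the 2034 horizon (HR 300, MR 200, LR 100), scaled
#' by 1.5 at 2054 and 2 at 2074.
#'
#' @param class Risk class ("LR", "MR" or "HR").
#' @param horizon Horizon year.
#' @return Radius in km.
#' @export
default_radius_rule <- function(class, horizon) {
  base <- c(LR = 100, MR = 200, HR = 300)
  mult <- c(`2034` = 1, `2054` = 1.5, `2074` = 2)
  if (!all(class %in% names(base))) stop("invalid risk class", call. = FALSE)
  if (!all(as.character(horizon) %in% names(mult)))
    stop("invalid horizon", call. = FALSE)
  unname(base[class] * mult[as.character(horizon)])
}

#' Circular buffer zones around at-risk country centroids
#'
#' Builds one geodesic circle per at-risk country (HR and MR by default) at
#' the given horizon, with radii from the radius rule.
#'
#' @param fixture A risk fixture data frame.
#' @param horizon Horizon year.
#' @param radius_rule Function `(class, horizon) -> km`.
#' @param classes Risk classes to include.
#' @param n_vertices Vertices per circle polygon.
#' @return A list of features, each with `country`, `class`, `radius_km` and
#'   a closed `ring` (matrix of lon/lat vertices); class `buffer_zones`.
#' @export
buffer_zones <- function(fixture, horizon, radius_rule = default_radius_rule,
                         classes = c("HR", "MR"), n_vertices = 72L) {
  col <- paste0("risk_", horizon)
  if (!col %in% names(fixture)) stop("fixture lacks column ", col,
                                     call. = FALSE)
  keep <- which(as.character(fixture[[col]]) %in% classes)
  feats <- lapply(keep, function(i) {
    cls <- as.character(fixture[[col]][i])
    r_km <- radius_rule(cls, horizon)
    bearings <- seq(0, 360, length.out = n_vertices + 1)
    ring <- geosphere::destPoint(c(fixture$lon[i], fixture$lat[i]),
                                 b = bearings, d = r_km * 1000)
    colnames(ring) <- c("lon", "lat")
    list(country = fixture$country[i], class = cls, radius_km = r_km,
         horizon = horizon, ring = ring)
  })
  structure(feats, class = "buffer_zones", horizon = horizon)
}

#' Joint temperature / maize area / spread series
#'
#' Aligns the warming schedule, the maize expansion curve and the spread
#' percentage into one annual table (the three-axis correlation view).
#'
#' @param years Year range (default 2024-2054).
#' @param schedule A [warming_schedule()].
#' @param curve A [maize_growth_curve()].
#' @param spread Either a data frame with `year` and `spread_pct` covering
#'   `years`, or a [logistic_params()] used to evaluate the closed form.
#' @return Data frame with columns `year`, `delta_t_c`, `maize_kha`,
#'   `spread_pct`.
#' @export
joint_series <- function(years = 2024:2054,
                         schedule = warming_schedule(),
                         curve = maize_growth_curve(),
                         spread = logistic_params()) {
  spread_pct <- if (is.data.frame(spread)) {
    i <- match(years, spread$year)
    if (anyNA(i)) stop("spread series does not cover the requested years",
                       call. = FALSE)
    spread$spread_pct[i]
  } else {
    100 * logistic_fraction(years - spread$start_year, spread)
  }
  data.frame(year = years,
             delta_t_c = warming_delta(years, schedule),
             maize_kha = project_area(years, curve),
             spread_pct = spread_pct)
}
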