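# Packaged fixtures: country centroids with per-horizon risk classes, and a
# synthetic per-country maize area table.

RISK_LEVELS <- c("LR", "MR", "HR")
RISK_HORIZONS <- c(2034L, 2054L, 2074L)

#' Load the country-centroid risk fixture
#'
#' Returns the packaged table of 29 European country centroids (WGS84
#' lon/lat, World Countries Centroids convention) with their low/medium/high
#' risk class (`LR < MR < HR`) at the 2034, 2054 and 2074 horizons. Risk
#' columns are ordered factors.
#'
#' @param path Optional path to an alternative CSV with the same columns.
#' @return A data frame with columns `country`, `lon`, `lat`, `risk_2034`,
#'   `risk_2054`, `risk_2074`.
#' @examples
#' head(load_centroid_fixture())
#' @export
load_centroid_fixture <- function(path = NULL) {
  path <- path %||% system.file("extdata", "country_centroids_risk.csv",
                                package = "dvvrisk", mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "lon", "lat", "risk_2034", "risk_2054", "risk_2074")
  if (!all(need %in% names(x)))
    stop("fixture corrupted: missing columns ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  if (nrow(x) != 29)
    stop(sprintf("fixture corrupted: expected 29 rows, found %d", nrow(x)),
         call. = FALSE)
  for (h in RISK_HORIZONS) {
    col <- paste0("risk_", h)
    if (!all(x[[col]] %in% RISK_LEVELS))
      stop("fixture corrupted: unknown risk class in ", col, call. = FALSE)
    x[[col]] <- factor(x[[col]], levels = RISK_LEVELS, ordered = TRUE)
  }
  x
}

#' Load the synthetic per-country maize area fixture
#'
#' A synthetic stand-in for official area statistics: for each country, the
#' last two annual maize areas (million ha). The final area in thousand ha
#' and its cultivation band are derived on load with
#' [estimate_final_area()] and [band_of()].
#'
#' @param path Optional path to an alternative CSV with the same columns.
#' @return A data frame with columns `country`, `lon`, `lat`, `area_y1_mha`,
#'   `area_y2_mha`, `final_area_kha`, `band`.
#' @export
load_maize_area_fixture <- function(path = NULL) {
  path <- path %||% system.file("extdata", "maize_areas_synthetic.csv",
                                package = "dvvrisk", mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$final_area_kha <- vapply(seq_len(nrow(x)), function(i)
    estimate_final_area(c(x$area_y1_mha[i], x$area_y2_mha[i])), numeric(1))
  x$band <- band_of(x$final_area_kha)
  x
}

#' Write a risk-record table to CSV
#'
#' Plain CSV writer used for fixture round-trips and pipeline output; factor
#' columns are written as their labels.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_risk_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
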