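# Logistic growth of the infested fraction of suitable area, and its spatial
# realisation as a distance-constrained cellular spread.

#' Logistic growth parameters for the infested fraction
#'
#' Defaults are calibrated so that starting from 40% of suitable area
#' infested at 2024, 95% is reached 30 years later
#' (`r = fit_logistic_rate(0.40, 0.95, 30)`).
#'
#' @param p0 Initial infested fraction of suitable area at the start year.
#' @param r Intrinsic growth rate per year.
#' @param k Carrying-capacity fraction (asymptote).
#' @param start_year Calendar year at which `t = 0` (default 2024).
#' @return An object of class `logistic_params`.
#' @export
logistic_params <- function(p0 = 0.40, r = 0.1117, k = 1.0,
                            start_year = 2024L) {
  if (!(p0 > 0 && p0 < k && k <= 1)) stop("need 0 < p0 < k <= 1",
                                          call. = FALSE)
  if (r < 0) stop("r must be >= 0", call. = FALSE)
  structure(list(p0 = p0, r = r, k = k, start_year = as.integer(start_year)),
            class = "logistic_params")
}

#' Logistic infested fraction at time t
#'
#' `P(t) = k / (1 + ((k - p0)/p0) * exp(-r t))`; strictly increasing in `t`
#' for `r > 0` with asymptote `k`.
#'
#' @param t_years Years since the start (vectorised, `t >= 0`).
#' @param params A [logistic_params()].
#' @return Fraction(s) in `(0, k)`.
#' @examples
#' logistic_fraction(30) # ~0.95 with defaults
#' @export
logistic_fraction <- function(t_years, params = logistic_params()) {
  stopifnot(all(t_years >= 0))
  params$k / (1 + ((params$k - params$p0) / params$p0) *
                exp(-params$r * t_years))
}

#' Solve for the logistic rate hitting a target fraction at time t
#'
#' Closed form: `r = log((p_t/(k - p_t)) / (p0/(k - p0))) / t`, so that
#' [logistic_fraction()] passes exactly through `(t, p_target)`.
#'
#' @param p0 Initial fraction.
#' @param p_target Target fraction at time `t` (`p0 < p_target < k`).
#' @param t Time in years.
#' @param k Carrying capacity.
#' @return The rate `r` per year.
#' @examples
#' fit_logistic_rate(0.40, 0.95, 30)
#' @export
fit_logistic_rate <- function(p0, p_target, t, k = 1.0) {
  if (!(p0 > 0 && p0 < p_target && p_target < k))
    stop("need 0 < p0 < p_target < k", call. = FALSE)
  log((p_target / (k - p_target)) / (p0 / (k - p0))) / t
}

#' Least-squares refit of a logistic series
#'
#' Recovers `p0` and `r` from a (possibly noisy) series of infested
#' fractions by Levenberg-Marquardt least squares with the carrying capacity
#' held fixed.
#'
#' @param t_years Time points (years since start).
#' @param p Observed fractions.
#' @param k Fixed carrying capacity.
#' @return A list with elements `p0` and `r`.
#' @export
fit_logistic_series <- function(t_years, p, k = 1.0) {
  df <- data.frame(t = t_years, p = p)
  start <- list(p0 = min(max(p[which.min(t_years)], 0.05), 0.9 * k), r = 0.1)
  fit <- minpack.lm::nlsLM(
    p ~ k / (1 + ((k - p0) / p0) * exp(-r * t)),
    data = df, start = start,
    lower = c(p0 = 1e-6, r = 0), upper = c(p0 = k - 1e-6, r = 5))
  as.list(stats::coef(fit))
}

#' Dispersal configuration for the cellular spread
#'
#' @param annual_radius_km New infestations must lie within this haversine
#'   distance of an already-infested cell.
#' @param stochastic If TRUE, new cells are drawn at random (seeded) from the
#'   eligible frontier instead of nearest-first.
#' @param seed Seed for the stochastic variant.
#' @return An object of class `dispersal_config`.
#' @export
dispersal_config <- function(annual_radius_km = 50, stochastic = FALSE,
                             seed = 42L) {
  if (annual_radius_km < 0) stop("annual_radius_km must be >= 0",
                                 call. = FALSE)
  structure(list(annual_radius_km = annual_radius_km,
                 stochastic = stochastic, seed = as.integer(seed)),
            class = "dispersal_config")
}

#' Infestation state raster
#'
#' @param grid A [grid_spec()].
#' @param first_year Integer matrix `(nlat, nlon)` of the year each cell was
#'   first infested; 0 means never infested.
#' @param horizon The year the state represents.
#' @return An object of class `infestation_state`.
#' @export
infestation_state <- function(grid, first_year, horizon) {
  stopifnot(inherits(grid, "grid_spec"),
            identical(dim(first_year), c(grid$nrow, grid$ncol)))
  if (any(first_year > horizon))
    stop("first-infestation years must not exceed the horizon", call. = FALSE)
  structure(list(grid = grid, first_year = first_year,
                 horizon = as.integer(horizon)),
            class = "infestation_state")
}

#' @export
print.infestation_state <- function(x, ...) {
  cat(sprintf("<infestation_state> %d: %d / %d cells infested\n",
              x$horizon, sum(x$first_year > 0), length(x$first_year)))
  invisible(x)
}

# Cell-centre coordinates of TRUE entries of a logical matrix, as a matrix
# with columns lon, lat plus row/col indices.
which_cells <- function(grid, m) {
  idx <- which(m, arr.ind = TRUE)
  cbind(lon = grid$lon[idx[, 2]], lat = grid$lat[idx[, 1]],
        row = idx[, 1], col = idx[, 2])
}

# Frontier = infested cells with at least one non-infested 8-neighbour (or
# on the grid edge); min distance from outside cells to the infested set is
# attained there.
frontier_cells <- function(inf) {
  nr <- nrow(inf); nc <- ncol(inf)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- inf
  all_nb <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    all_nb <- all_nb & pad[2:(nr + 1) + di, 2:(nc + 1) + dj]
  }
  inf & !all_nb
}

#' Simulate constrained cellular spread toward a logistic target
#'
#' Each year the target infested cell count is
#' `round(logistic_fraction(year - start) * n_suitable)`. New cells are drawn
#' from suitable, not-yet-infested cells within `annual_radius_km` of the
#' current infestation frontier, nearest first (haversine distance to the
#' frontier), ties broken lexicographically by (lat, lon). Infestation is
#' never revoked. If the reachable frontier is exhausted before the target is
#' met, what is reachable is filled and the shortfall recorded in the
#' returned attribute `shortfall`.
#'
#' @param seed_state An [infestation_state()] at the start year.
#' @param suitability A logical matrix / `suitability_mask`, or a named list
#'   of them (names = years) for year-varying suitability.
#' @param params A [logistic_params()] with `start_year` equal to the seed
#'   state's horizon.
#' @param dispersal A [dispersal_config()].
#' @param years Increasing vector of years after the seed horizon.
#' @return A named list of [infestation_state()] per year, with attribute
#'   `shortfall` (data frame year/missing, possibly empty).
#' @export
simulate_spread <- function(seed_state, suitability,
                            params = logistic_params(),
                            dispersal = dispersal_config(),
                            years) {
  stopifnot(inherits(seed_state, "infestation_state"))
  grid <- seed_state$grid
  years <- sort(as.integer(years))
  if (length(years) && years[1] <= seed_state$horizon)
    stop("years must follow the seed state's horizon", call. = FALSE)
  get_suit <- function(y) {
    s <- if (is.list(suitability) && !inherits(suitability, "suitability_mask"))
      suitability[[as.character(y)]] else suitability
    if (is.null(s)) stop("no suitability layer for year ", y, call. = FALSE)
    if (inherits(s, "suitability_mask")) s$mask else s
  }
  fy <- seed_state$first_year
  if (any(fy > 0 & !get_suit(years[1])))
    stop("seed cells must be a subset of suitable cells", call. = FALSE)
  out <- vector("list", length(years)); names(out) <- years
  shortfall <- data.frame(year = integer(), missing = integer())
  for (i in seq_along(years)) {
    y <- years[i]
    suit <- get_suit(y)
    inf <- fy > 0
    n_suit <- sum(suit)
    target <- round(logistic_fraction(y - params$start_year, params) * n_suit)
    need <- target - sum(inf)
    if (need > 0 && dispersal$annual_radius_km > 0 && any(inf)) {
      cand <- which_cells(grid, suit & !inf)
      if (nrow(cand) > 0) {
        fr <- which_cells(grid, frontier_cells(inf))
        # prefilter by a bounding box in degrees around the frontier
        margin <- dispersal$annual_radius_km / 111.19 + grid$res
        keep <- cand[, "lon"] >= min(fr[, "lon"]) - margin /
                  cos(max(abs(fr[, "lat"])) * pi / 180) &
                cand[, "lon"] <= max(fr[, "lon"]) + margin /
                  cos(max(abs(fr[, "lat"])) * pi / 180) &
                cand[, "lat"] >= min(fr[, "lat"]) - margin &
                cand[, "lat"] <= max(fr[, "lat"]) + margin
        cand <- cand[keep, , drop = FALSE]
      }
      if (nrow(cand) > 0) {
        d <- geosphere::distm(cand[, c("lon", "lat"), drop = FALSE],
                              fr[, c("lon", "lat"), drop = FALSE],
                              fun = geosphere::distHaversine)
        dmin <- apply(d, 1, min) / 1000
        eligible <- dmin <= dispersal$annual_radius_km
        cand <- cand[eligible, , drop = FALSE]
        dmin <- dmin[eligible]
        take <- min(need, nrow(cand))
        if (take > 0) {
          ord <- if (dispersal$stochastic)
            withr::with_seed(child_seed(dispersal$seed, y),
                             sample(nrow(cand)))
          else
            order(dmin, cand[, "lat"], cand[, "lon"])
          sel <- cand[ord[seq_len(take)], , drop = FALSE]
          fy[cbind(sel[, "row"], sel[, "col"])] <- y
        }
        if (take < need)
          shortfall <- rbind(shortfall,
                             data.frame(year = y, missing = need - take))
      } else {
        shortfall <- rbind(shortfall,
                           data.frame(year = y, missing = need))
      }
    } else if (need > 0) {
      shortfall <- rbind(shortfall, data.frame(year = y, missing = need))
    }
    out[[i]] <- infestation_state(grid, fy, y)
  }
  if (nrow(shortfall))
    message("spread shortfall in ", nrow(shortfall),
            " year(s); frontier exhausted")
  attr(out, "shortfall") <- shortfall
  out
}

AFFECTED_LEVELS <- c("unaffected", "newly", "recently", "longer")

#' Affected-age categories of an infestation state
#'
#' Classifies each cell by how long it has been infested at the horizon:
#' newly affected (infested within the last 5 years), recently affected
#' (5-15 years), longer affected (more than 15 years), or unaffected. The
#' 5/15-year band edges are conventions recorded in the result's attributes.
#'
#' @param state An [infestation_state()].
#' @param horizon Horizon year (defaults to the state's own).
#' @param bands Numeric `c(newly, recently)` band edges in years.
#' @return A character matrix (values unaffected/newly/recently/longer) with
#'   attributes `bands` and `levels`.
#' @export
affected_categories <- function(state, horizon = state$horizon,
                                bands = c(5, 15)) {
  fy <- state$first_year
  if (any(fy > horizon))
    stop("first-infestation years exceed the horizon", call. = FALSE)
  cls <- ifelse(fy == 0, "unaffected",
         ifelse(fy > horizon - bands[1], "newly",
         ifelse(fy > horizon - bands[2], "recently", "longer")))
  out <- matrix(cls, nrow(fy), ncol(fy))
  attr(out, "bands") <- bands
  attr(out, "levels") <- AFFECTED_LEVELS
  out
}

#' Infested percentage of suitable area per year
#'
#' @param states List of [infestation_state()] (as from [simulate_spread()]).
#' @param suitability Logical matrix / mask, or named list per year.
#' @return Data frame with columns `year`, `infested_cells`,
#'   `suitable_cells`, `spread_pct`.
#' @export
spread_series <- function(states, suitability) {
  rows <- lapply(states, function(s) {
    m <- if (is.list(suitability) && !inherits(suitability, "suitability_mask"))
      suitability[[as.character(s$horizon)]] else suitability
    if (inherits(m, "suitability_mask")) m <- m$mask
    ns <- sum(m)
    if (ns == 0) stop("no suitable cells; spread percentage undefined",
                      call. = FALSE)
    data.frame(year = s$horizon, infested_cells = sum(s$first_year > 0),
               suitable_cells = ns,
               spread_pct = 100 * sum(s$first_year > 0) / ns)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
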