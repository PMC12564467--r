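# Shared fixture builders and independent oracles, constructed in code.

# A climate_grid with identical monthly values in every cell.
const_grid <- function(monthly, grid = grid_spec(20, 24, 44, 48, 1),
                       tmax = NULL, year = NULL) {
  stopifnot(length(monthly) == 12)
  tm <- array(rep(monthly, each = grid$nrow * grid$ncol),
              dim = c(grid$nrow, grid$ncol, 12))
  tx <- if (!is.null(tmax))
    array(rep(tmax, each = grid$nrow * grid$ncol),
          dim = c(grid$nrow, grid$ncol, 12))
  climate_grid(grid, tm, tmax = tx, year = year)
}

# A seeded random climate_grid (iid monthly values, for oracle-equality
# properties that need no spatial structure).
random_grid <- function(grid = grid_spec(20, 24, 44, 48, 1), seed = 1,
                        mean = 10, sd = 8) {
  withr::with_seed(seed, climate_grid(
    grid, array(stats::rnorm(grid$nrow * grid$ncol * 12, mean, sd),
                dim = c(grid$nrow, grid$ncol, 12))))
}

# Brute-force persistence oracle: scan every possible run start explicitly.
persistence_oracle <- function(monthly, threshold, k, window = c(4, 9)) {
  months <- window[1]:window[2]
  ok <- FALSE
  for (s in seq_len(length(months) - k + 1)) {
    run <- monthly[months[s:(s + k - 1)]]
    if (all(run >= threshold)) ok <- TRUE
  }
  ok
}

# Forward-Euler integration of dP/dt = r P (1 - P/k).
euler_logistic <- function(p0, r, k, t_end, dt = 0.01) {
  p <- p0
  for (i in seq_len(round(t_end / dt))) p <- p + dt * r * p * (1 - p / k)
  p
}

# All-suitable seed state with n seed cells nearest an origin.
seeded_state <- function(grid, suit, n_seed, origin = c(20.5, 44.8),
                        year = 2024L) {
  cells <- which(suit, arr.ind = TRUE)
  d <- geosphere::distHaversine(
    cbind(grid$lon[cells[, 2]], grid$lat[cells[, 1]]), origin)
  ord <- order(d, cells[, 1], cells[, 2])
  fy <- matrix(0L, grid$nrow, grid$ncol)
  sel <- cells[ord[seq_len(n_seed)], , drop = FALSE]
  fy[sel] <- year
  infestation_state(grid, fy, year)
}
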