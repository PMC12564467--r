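# Warming schedule, anomalies, GDD and warm-season statistics.

test_that("warming schedule reproduces the 5-year table and extrapolates", {
  expect_equal(warming_delta(2024), 1.4)
  expect_equal(warming_delta(2054), 2.6)
  expect_equal(warming_delta(2074), 3.4)  # linear extrapolation
  # affine: every 5-year increment equals the step
  ys <- seq(2024, 2094, 1)
  expect_equal(warming_delta(ys + 5) - warming_delta(ys),
               rep(0.2, length(ys)))
  expect_error(warming_delta(2023), "anchor")
})

test_that("apply_warming is an exact shift and commutes with seasonal means", {
  g <- random_grid(seed = 3)
  expect_equal(apply_warming(g, 0), g)
  expect_equal(apply_warming(apply_warming(g, 1.4), -1.4)$tmean, g$tmean)
  expect_equal(warm_season_mean(apply_warming(g, 2.2)),
               warm_season_mean(g) + 2.2)
  expect_error(apply_warming(g, NA), "finite")
})

test_that("anomaly_map matches a direct two-mean oracle", {
  g <- grid_spec(res = 5)
  p <- climatology_params(noise_sd = 0.5, trend_per_year = 0.04, seed = 11L)
  s <- generate_annual_series(g, p, 1991:2024)

  # anomaly of the reference against itself is identically zero
  ref <- reference_period()
  expect_equal(anomaly_map(s, list(start = 1991, end = 2020), ref),
               matrix(0, g$nrow, g$ncol), tolerance = 1e-12)

  # uniform offset in the period years shows up exactly
  s2 <- s
  s2[["2024"]] <- apply_warming(s2[["2024"]], 1.0)
  d <- anomaly_map(s2, list(start = 2024, end = 2024)) -
    anomaly_map(s, list(start = 2024, end = 2024))
  expect_equal(d, matrix(1, g$nrow, g$ncol))

  # brute-force oracle: loop over years and cells independently
  period <- list(start = 1992, end = 2024)
  oracle <- {
    am <- function(y) apply(s[[as.character(y)]]$tmean, c(1, 2), mean)
    Reduce(`+`, lapply(1992:2024, am)) / length(1992:2024) -
      Reduce(`+`, lapply(1991:2020, am)) / 30
  }
  expect_equal(anomaly_map(s, period), oracle, tolerance = 1e-9)

  expect_error(anomaly_map(s, list(start = 1980, end = 1990)), "cover")
})

test_that("GDD accumulates heat above base on a non-leap calendar", {
  warm_season <- c(0, 0, 0, 20, 20, 20, 20, 20, 20, 0, 0, 0)
  expect_equal(gdd(warm_season, base = 10), 10 * 183)
  expect_equal(gdd(rep(10, 12), base = 10), 0)
  expect_error(gdd(rep(10, 11)), "12 monthly")

  g <- random_grid(seed = 5)
  # monotone in base, cellwise
  expect_true(all(gdd(g, 10) >= gdd(g, 12)))
  # translation consistency: gdd(T + c, base + c) = gdd(T, base)
  expect_equal(gdd(apply_warming(g, 3.7), base = 13.7), gdd(g, base = 10))
})

test_that("warm-season mean equals the month-loop oracle", {
  expect_equal(warm_season_mean(const_grid(rep(15, 12)))[1, 1], 15)
  apr_sep <- c(0, 0, 0, 10, 12, 14, 16, 18, 20, 0, 0, 0)
  expect_equal(warm_season_mean(const_grid(apr_sep))[2, 2], 15)

  g <- random_grid(seed = 9)
  oracle <- Reduce(`+`, lapply(4:9, function(m) g$tmean[, , m])) / 6
  expect_equal(warm_season_mean(g), oracle)
})

test_that("presence/anomaly overlap counts points per cell", {
  g <- grid_spec(0, 4, 40, 44, 1)
  dat <- matrix(2, g$nrow, g$ncol)  # uniformly above threshold
  pts <- data.frame(lon = c(0.5, 1.5, 2.5), lat = c(40.5, 41.5, 42.5))
  expect_equal(presence_anomaly_overlap(pts, dat, g, 1), 1.0)

  # checkerboard with half the points above the threshold
  dat2 <- outer(1:4, 1:4, function(r, c) ifelse((r + c) %% 2 == 0, 2, 0))
  pts2 <- data.frame(lon = c(0.5, 1.5), lat = c(40.5, 40.5))
  expect_equal(presence_anomaly_overlap(pts2, dat2, g, 1), 0.5)

  # out-of-grid points warned and excluded from the denominator
  pts3 <- data.frame(lon = c(1.5, 99), lat = c(40.5, 40.5))
  expect_warning(f <- presence_anomaly_overlap(pts3, dat2, g, 1), "outside")
  expect_equal(f, 0)  # only the in-grid point (a cold cell) counts
  expect_warning(
    expect_true(is.na(presence_anomaly_overlap(
      data.frame(lon = numeric(), lat = numeric()), dat, g, 1))),
    "undefined")
})

test_that("the six cumulative periods are as defined", {
  p <- period_definitions()
  expect_equal(p$label, paste0("P", 1:6))
  expect_equal(p$start, c(1991L, rep(1992L, 5)))
  expect_equal(p$end, c(1992L, 2002L, 2012L, 2020L, 2022L, 2024L))
})
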