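# Logistic growth model and distance-constrained cellular spread.

test_that("logistic fraction matches its closed form at the endpoints", {
  expect_equal(logistic_fraction(0), 0.40)
  expect_equal(logistic_fraction(0:30, logistic_params(r = 0)),
               rep(0.40, 31))
  expect_equal(logistic_fraction(30), 0.950, tolerance = 1e-3)
  expect_true(all(diff(logistic_fraction(0:50)) > 0))
  expect_error(logistic_params(p0 = 0), "0 < p0")
  expect_error(logistic_params(p0 = 1.2, k = 1), "0 < p0")
})

test_that("rate calibration round-trips through the logistic", {
  r <- fit_logistic_rate(0.40, 0.95, 30)
  expect_equal(r, 0.11166, tolerance = 1e-4)
  expect_equal(logistic_fraction(30, logistic_params(p0 = 0.40, r = r)),
               0.95, tolerance = 1e-12)
  # doubling the time halves the rate for fixed endpoints
  expect_equal(fit_logistic_rate(0.40, 0.95, 60), r / 2)
  # target near p0 drives the rate to zero
  expect_lt(fit_logistic_rate(0.40, 0.400001, 30), 1e-5)
  expect_error(fit_logistic_rate(0.40, 0.30, 30), "p0 < p_target")
})

test_that("logistic solution matches forward-Euler integration", {
  p <- logistic_params()
  for (t in c(10, 30, 50)) {
    euler <- euler_logistic(p$p0, p$r, p$k, t, dt = 0.01)
    expect_equal(logistic_fraction(t, p), euler, tolerance = 1e-3)
  }
})

test_that("least squares recovers the parameters from noisy series", {
  true <- logistic_params()
  t <- 0:30
  worst_r <- 0; worst_p0 <- 0
  for (seed in 1:100) {
    p_obs <- withr::with_seed(seed,
      logistic_fraction(t, true) + rnorm(31, sd = 0.01))
    fit <- fit_logistic_series(t, p_obs)
    worst_r <- max(worst_r, abs(fit$r - true$r) / true$r)
    worst_p0 <- max(worst_p0, abs(fit$p0 - true$p0))
  }
  expect_lt(worst_r, 0.10)
  expect_lt(worst_p0, 0.05)
})

test_that("spread is contained, monotone, and reaches close neighbours", {
  # single seed on a fully suitable 3x3 grid at 0.25 deg: all cell centres
  # lie within 60 km of the centre at ~45 N, so one uncapped step fills it
  g <- grid_spec(20, 20.75, 44.5, 45.25, 0.25)
  suit <- matrix(TRUE, 3, 3)
  fy <- matrix(0L, 3, 3); fy[2, 2] <- 2024L
  st <- infestation_state(g, fy, 2024L)
  res <- simulate_spread(st, suit,
                         logistic_params(p0 = 0.5, r = 10),
                         dispersal_config(60), years = 2025)
  expect_equal(sum(res[["2025"]]$first_year > 0), 9)

  # radius 0 keeps the state constant
  res0 <- simulate_spread(st, suit, logistic_params(p0 = 0.5, r = 10),
                          dispersal_config(0), years = 2025:2027)
  for (s in res0) expect_equal(s$first_year, fy)
  expect_gt(nrow(attr(res0, "shortfall")), 0)

  # seed outside suitability is rejected
  bad_suit <- suit; bad_suit[2, 2] <- FALSE
  expect_error(simulate_spread(st, bad_suit, logistic_params(),
                               dispersal_config(60), 2025), "subset")
})

test_that("spread obeys containment and monotone growth on larger grids", {
  g <- grid_spec(10, 30, 40, 50, 1)
  suit <- withr::with_seed(8, matrix(runif(g$nrow * g$ncol) < 0.7,
                                     g$nrow, g$ncol))
  suit[5, 10] <- TRUE
  st <- seeded_state(g, suit, n_seed = round(0.2 * sum(suit)),
                     origin = c(20.5, 44.5))
  res <- suppressMessages(
    simulate_spread(st, suit, logistic_params(p0 = 0.2, r = 0.15),
                    dispersal_config(150), years = 2025:2040))
  prev <- st$first_year > 0
  for (s in res) {
    cur <- s$first_year > 0
    expect_true(all(cur[prev]))          # never revoked
    expect_true(all(suit[cur]))          # infested subset of suitable
    expect_true(all(s$first_year <= s$horizon))
    prev <- cur
  }
})

test_that("spread series tracks the logistic up to cell quantisation", {
  g <- grid_spec(0, 40, 40, 60, 1)
  suit <- matrix(TRUE, g$nrow, g$ncol)
  n <- sum(suit)
  lp <- logistic_params(p0 = 0.40, r = 0.1117)
  st <- seeded_state(g, suit, n_seed = round(lp$p0 * n),
                     origin = c(20, 45))
  res <- simulate_spread(st, suit, lp, dispersal_config(500),
                         years = 2025:2054)
  ss <- spread_series(res, suit)
  expect_true(all(diff(ss$spread_pct) >= 0))
  target <- 100 * logistic_fraction(ss$year - 2024, lp)
  expect_true(all(abs(ss$spread_pct - target) <= 100 * 1.5 / n))
  expect_equal(ss$spread_pct[ss$year == 2054], 95.0, tolerance = 0.2)

  # all-infested and seed-only arithmetic
  full <- infestation_state(g, matrix(2024L, g$nrow, g$ncol), 2024L)
  expect_equal(spread_series(list(full), suit)$spread_pct, 100)
  one <- matrix(0L, 20, 10); one[1, 1] <- 2024L
  g2 <- grid_spec(0, 10, 40, 60, 1)
  expect_equal(spread_series(list(infestation_state(g2, one, 2024L)),
                             matrix(TRUE, 20, 10))$spread_pct, 0.5)
  expect_error(spread_series(list(full), matrix(FALSE, g$nrow, g$ncol)),
               "no suitable")
})

test_that("affected categories partition cells by infestation age", {
  fy <- matrix(c(0L, 2054L, 2047L, 2035L), 2, 2)
  st <- infestation_state(grid_spec(0, 2, 40, 42, 1), fy, 2054L)
  cats <- affected_categories(st)
  expect_equal(cats[1, 1], "unaffected")
  expect_equal(cats[2, 1], "newly")      # infested at the horizon year
  expect_equal(cats[1, 2], "recently")   # 7 years before the horizon
  expect_equal(cats[2, 2], "longer")     # 19 years before the horizon
  expect_true(all(cats %in% c("unaffected", "newly", "recently", "longer")))
  # a cell infested exactly 10 years before the horizon is 'recently'
  fy2 <- matrix(2044L, 1, 1)
  st2 <- infestation_state(grid_spec(0, 1, 40, 41, 1), fy2, 2054L)
  expect_equal(affected_categories(st2)[1, 1], "recently")
})
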