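# Synthetic climate generator and packaged fixtures.

test_that("climatology hits its anchors and cools with latitude", {
  p0 <- climatology_params(noise_sd = 0)
  g45 <- grid_spec(20, 22, 44.5, 45.5, 1)  # single-row grid centred on 45 N
  cl45 <- generate_climatology(g45, p0)
  expect_equal(cl45$tmean[1, 1, 7], 22.0)  # July at 45 N is the anchor

  g55 <- grid_spec(20, 22, 54.5, 55.5, 1)
  cl55 <- generate_climatology(g55, p0)
  expect_equal(cl55$tmean[1, 1, 7], 22.0 - 0.7 * 10)

  # strict latitudinal monotonicity, every month, zero noise
  cl <- generate_climatology(grid_spec(res = 2.5), p0)
  for (m in 1:12)
    expect_true(all(diff(cl$tmean[, 1, m]) < 0))

  # July is the warmest month everywhere
  expect_true(all(apply(cl$tmean, c(1, 2), which.max) == 7))
})

test_that("generation is deterministic under a fixed seed", {
  g <- grid_spec(res = 5)
  p <- climatology_params(noise_sd = 0.5, seed = 7L)
  expect_identical(generate_climatology(g, p), generate_climatology(g, p))
  s1 <- generate_annual_series(g, p, 2000:2003)
  s2 <- generate_annual_series(g, p, 2000:2003)
  expect_identical(s1, s2)
  # a year's field does not depend on the requested range
  s3 <- generate_annual_series(g, p, 2002:2003)
  expect_identical(s1[["2002"]], s3[["2002"]])
})

test_that("annual series obeys the reference-period identity and trend", {
  g <- grid_spec(res = 5)
  p0 <- climatology_params(noise_sd = 0, trend_per_year = 0)
  cl <- generate_climatology(g, p0)
  s <- generate_annual_series(g, p0, 1991:2024)
  for (y in c("1991", "2005", "2024"))
    expect_equal(s[[y]]$tmean, cl$tmean)

  # 30-year reference mean minus climatology is 0 everywhere (noise = 0)
  pt <- climatology_params(noise_sd = 0, trend_per_year = 0.04)
  st <- generate_annual_series(g, pt, 1991:2024)
  ref_mean <- Reduce(`+`, lapply(1991:2020, function(y)
    st[[as.character(y)]]$tmean)) / 30
  expect_equal(ref_mean, cl$tmean, tolerance = 1e-12)

  # 2024 anomaly vs the reference equals trend x (2024 - 2005.5) = +0.74
  dat <- anomaly_map(st, list(start = 2024, end = 2024))
  expect_equal(unique(round(as.vector(dat), 9)), 0.74)
})

test_that("generator rejects invalid inputs", {
  expect_error(grid_spec(res = 0), "res")
  expect_error(grid_spec(res = -1), "res")
  expect_error(grid_spec(0, 10, 40, 45, res = 3), "integer multiple")
  expect_error(climatology_params(noise_sd = -1), ">= 0")
  expect_error(generate_annual_series(grid_spec(res = 5),
                                      years = integer(0)), "empty")
  expect_error(generate_annual_series(grid_spec(res = 5), years = 1950),
               "1991-2100")
})

test_that("presence history radiates from the origin", {
  h <- generate_presence_history(spread_rate = 0.35, seed = 1L)
  pts <- h$points
  # origin country (nearest centroid to Belgrade = Serbia) detected in 1992
  expect_equal(pts$first_year[pts$country == "Serbia"], 1992)
  # detection year non-decreasing in distance from the origin
  d <- geosphere::distHaversine(cbind(pts$lon, pts$lat), c(20.5, 44.8))
  det <- !is.na(pts$first_year)
  expect_true(all(diff(pts$first_year[det][order(d[det])]) >= 0))
  # statuses come from the closed six-value vocabulary
  expect_true(all(h$records$status %in%
                    c("absent", "widespread", "restricted",
                      "few_occurrences", "eradicated", "transient")))
  # zero spread rate: only the origin country is ever present
  h0 <- generate_presence_history(spread_rate = 0)
  expect_identical(h0$points$country[!is.na(h0$points$first_year)], "Serbia")
  expect_error(generate_presence_history(spread_rate = -1), ">= 0")
})

test_that("centroid fixture matches the reference table and round-trips", {
  fx <- load_centroid_fixture()
  expect_equal(nrow(fx), 29)
  serbia <- fx[fx$country == "Serbia", ]
  expect_equal(c(serbia$lon, serbia$lat), c(20.80, 44.00))
  expect_equal(as.character(unlist(serbia[paste0("risk_", c(2034, 2054, 2074))])),
               c("HR", "HR", "HR"))
  estonia <- fx[fx$country == "Estonia", ]
  expect_equal(c(estonia$lon, estonia$lat), c(25.00, 58.60))
  expect_equal(as.character(unlist(estonia[paste0("risk_", c(2034, 2054, 2074))])),
               c("LR", "LR", "LR"))
  expect_equal(fx$lon[fx$country == "Spain"], -4.00)
  expect_true(all(fx$lat >= 35 & fx$lat <= 60))
  # severity never decreases across horizons in the reference table
  expect_true(all(fx$risk_2054 >= fx$risk_2034))
  expect_true(all(fx$risk_2074 >= fx$risk_2054))

  # CSV round trip preserves the fixture exactly
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_risk_csv(fx, tmp)
  expect_equal(load_centroid_fixture(tmp), fx)

  # truncated or mangled fixtures are rejected
  write_risk_csv(fx[-1, ], tmp)
  expect_error(load_centroid_fixture(tmp), "29")
  fx_bad <- fx
  fx_bad$risk_2034 <- as.character(fx_bad$risk_2034)
  fx_bad$risk_2034[1] <- "XX"
  write_risk_csv(fx_bad, tmp)
  expect_error(load_centroid_fixture(tmp), "unknown risk class")
})

test_that("maize area fixture derives bands consistently", {
  mx <- load_maize_area_fixture()
  expect_equal(mx$final_area_kha[mx$country == "Romania"], 2500)
  expect_true(all(mx$band == band_of(mx$final_area_kha)))
  expect_true(all(mx$final_area_kha >= 0))
})
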