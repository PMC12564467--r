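# End-to-end pipeline: synthetic climate -> anomalies -> suitability ->
# spread -> risk tables and buffer zones, with a manifest of every parameter
# used.

#' Pipeline configuration
#'
#' A flat list of every tunable the pipeline uses, serializable with
#' [write_config()] / [read_config()]. Defaults are the package's study
#' conditions: the Europe grid, the synthetic climatology, the 12.5/9 °C
#' persistence thresholds, the logistic spread defaults and the three risk
#' horizons.
#'
#' @param lon_min,lon_max,lat_min,lat_max,res Grid box and resolution
#'   (degrees).
#' @param sea_level_july_temp,lapse_per_lat,seasonal_amplitude,noise_sd,trend_per_year
#'   Climatology parameters (see [climatology_params()]).
#' @param anchor_year,anchor_delta,step_per_5yr Warming schedule (see
#'   [warming_schedule()]).
#' @param activity_min,establishment_min,persistence_months Beetle thresholds.
#' @param germination_min,heat_stress_max,gdd_lo,gdd_base,tmax_offset Maize
#'   thresholds.
#' @param p0,r,k Logistic spread parameters.
#' @param annual_radius_km Dispersal radius.
#' @param origin_lon,origin_lat Invasion origin (near Belgrade).
#' @param horizons Risk horizons.
#' @param category_years Years at which affected-category layers are written.
#' @param seed Master seed.
#' @return An object of class `pipeline_config` (a flat named list).
#' @export
pipeline_config <- function(lon_min = -10, lon_max = 40, lat_min = 35,
                            lat_max = 70, res = 0.25,
                            sea_level_july_temp = 22, lapse_per_lat = 0.7,
                            seasonal_amplitude = 10, noise_sd = 0.5,
                            trend_per_year = 0.04,
                            anchor_year = 2024L, anchor_delta = 1.4,
                            step_per_5yr = 0.2,
                            activity_min = 12.5, establishment_min = 9,
                            persistence_months = 2L,
                            germination_min = 10, heat_stress_max = 35,
                            gdd_lo = 1000, gdd_base = 10, tmax_offset = 6,
                            p0 = 0.40, r = 0.1117, k = 1.0,
                            annual_radius_km = 50,
                            origin_lon = 20.5, origin_lat = 44.8,
                            horizons = c(2034L, 2054L, 2074L),
                            category_years = c(2029L, 2034L, 2039L, 2049L,
                                               2054L),
                            seed = 42L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

stage <- function(name, created, expr) {
  tryCatch(expr, error = function(e) {
    unlink(created(), force = TRUE)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Chains every stage over synthetic inputs and writes, under `out_dir`:
#' anomaly (DAT) rasters for the six cumulative periods, beetle and maize
#' suitability masks per horizon, yearly spread states with affected-category
#' layers at the category years, the joint temperature/maize/spread CSV, the
#' country risk CSV with its agreement report, buffer-zone GeoJSONs per
#' horizon, and a YAML manifest echoing every parameter and derived
#' calibration. Any stage error aborts with the stage name and removes the
#' files created so far.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the key in-memory results (`cuts`,
#'   `risk`, `series`, `spread_states`, `masks`) and `files` (all paths
#'   written).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  created <- function() files
  out <- function(...) file.path(out_dir, sprintf(...))
  add <- function(p) files <<- c(files, p)

  grid <- stage("grid", created, grid_spec(config$lon_min, config$lon_max,
                                           config$lat_min, config$lat_max,
                                           config$res))
  cl_par <- climatology_params(config$sea_level_july_temp,
                               config$lapse_per_lat,
                               config$seasonal_amplitude, config$noise_sd,
                               config$trend_per_year, config$seed)
  schedule <- warming_schedule(config$anchor_year, config$anchor_delta,
                               config$step_per_5yr)
  pest_th <- pest_thresholds(activity_min = config$activity_min,
                             establishment_min = config$establishment_min,
                             persistence_months = config$persistence_months)
  maize_th <- maize_thresholds(germination_min = config$germination_min,
                               heat_stress_max = config$heat_stress_max,
                               gdd_lo = config$gdd_lo,
                               gdd_base = config$gdd_base,
                               tmax_offset = config$tmax_offset)

  # --- historical anomalies -------------------------------------------------
  series <- stage("annual_series", created,
                  generate_annual_series(grid, cl_par, 1991:2024))
  periods <- period_definitions()
  for (i in seq_len(nrow(periods))) {
    dat <- stage(paste0("anomaly_", periods$label[i]), created,
                 anomaly_map(series, periods[i, ]))
    add(write_ascii_grid(dat, grid,
                         out("dat_%s_%d_%d.asc", periods$label[i],
                             periods$start[i], periods$end[i])))
  }

  # --- projected grids and suitability masks per horizon --------------------
  base_2024 <- series[["2024"]]
  masks <- list()
  for (h in config$horizons) {
    extra <- warming_delta(h, schedule) -
      warming_delta(config$anchor_year, schedule)
    proj <- stage("projection", created, apply_warming(base_2024, extra))
    pm <- stage("pest_suitability", created,
                pest_suitability_mask(proj, pest_th))
    mm <- stage("maize_suitability", created,
                maize_suitability_mask(proj, maize_th))
    masks[[as.character(h)]] <- list(pest = pm, maize = mm)
    add(write_ascii_grid(pm$activity$mask + 0, grid,
                         out("suit_activity_%d.asc", h)))
    add(write_ascii_grid(pm$establishment$mask + 0, grid,
                         out("suit_establishment_%d.asc", h)))
    add(write_ascii_grid(mm$mask + 0, grid, out("suit_maize_%d.asc", h)))
  }

  # --- spread simulation 2024 -> last category year -------------------------
  spread_res <- stage("spread", created, {
    suit <- pest_suitability_mask(base_2024, pest_th)$establishment$mask
    n_seed <- round(config$p0 * sum(suit))
    cells <- which_cells(grid, suit)
    d0 <- geosphere::distHaversine(cells[, c("lon", "lat"), drop = FALSE],
                                   c(config$origin_lon, config$origin_lat))
    ord <- order(d0, cells[, "lat"], cells[, "col"])
    fy <- matrix(0L, grid$nrow, grid$ncol)
    sel <- cells[ord[seq_len(n_seed)], , drop = FALSE]
    fy[cbind(sel[, "row"], sel[, "col"])] <- config$anchor_year
    seed_state <- infestation_state(grid, fy, config$anchor_year)
    lp <- logistic_params(config$p0, config$r, config$k, config$anchor_year)
    dc <- dispersal_config(config$annual_radius_km, seed = config$seed)
    yrs <- (config$anchor_year + 1):max(config$category_years)
    states <- simulate_spread(seed_state, suit, lp, dc, yrs)
    list(seed_state = seed_state, states = states, suit = suit, lp = lp)
  })
  for (h in config$category_years) {
    cat_m <- affected_categories(spread_res$states[[as.character(h)]])
    codes <- matrix(match(cat_m, attr(cat_m, "levels")) - 1L,
                    grid$nrow, grid$ncol)
    add(write_ascii_grid(codes, grid, out("affected_categories_%d.asc", h)))
    add(write_ascii_grid(spread_res$states[[as.character(h)]]$first_year,
                         grid, out("first_infestation_%d.asc", h)))
  }

  # --- joint series CSV -----------------------------------------------------
  sseries <- stage("series", created, {
    ss <- spread_series(c(list(spread_res$seed_state), spread_res$states),
                        spread_res$suit)
    js <- joint_series(ss$year, schedule, maize_growth_curve(),
                       data.frame(year = ss$year,
                                  spread_pct = ss$spread_pct))
    utils::write.csv(js, out("joint_series.csv"), row.names = FALSE)
    add(out("joint_series.csv"))
    js
  })

  # --- centroid risk classification and buffers -----------------------------
  fixture <- stage("risk_fixture", created, load_centroid_fixture())
  cuts <- stage("calibration", created,
                calibrate_latitude_cuts(fixture, config$horizons))
  risk <- stage("risk_table", created, risk_table(fixture, cuts))
  add(write_risk_csv(risk, out("country_risk.csv")))
  add(write_geojson_points(fixture[, c("country", "lon", "lat")],
                           out("country_centroids.geojson")))
  for (h in config$horizons) {
    bz <- stage("buffers", created, buffer_zones(fixture, h))
    add(write_geojson_polygons(
      bz, out("buffer_zones_%d.geojson", h),
      metadata = list(radius_rule = "HR 300 / MR 200 / LR 100 km at 2034, x1.5 at 2054, x2 at 2074",
                      classes = c("HR", "MR"))))
  }

  # --- manifest -------------------------------------------------------------
  manifest <- list(
    config = unclass(config),
    derived = list(
      latitude_cuts = as.list(as.data.frame(cuts)),
      agreement = as.list(attr(risk, "agreement")),
      affected_category_bands_years = c(5, 15),
      maize_growth_rate_per_year = log(20 / 6) / 30,
      n_suitable_cells_2024 = sum(spread_res$suit),
      shortfall_years = attr(spread_res$states, "shortfall")$year))
  yaml::write_yaml(manifest, out("manifest.yml"))
  add(out("manifest.yml"))

  invisible(list(cuts = cuts, risk = risk, series = sseries,
                 spread_states = spread_res$states, masks = masks,
                 files = files))
}
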