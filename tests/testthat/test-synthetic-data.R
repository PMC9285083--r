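test_that("configuration validation rejects impossible settings", {
  expect_error(simulation_config(stage_date_sd = -1), "negative SD",
               class = "primecrop_config_error")
  expect_error(simulation_config(stage_date_means = c(200, 150, 240, 265)),
               "strictly increasing", class = "primecrop_config_error")
  expect_error(simulation_config(missing_rate = 1),
               class = "primecrop_config_error")
  expect_error(simulation_config(priming_mitigation_frac = 1.2),
               class = "primecrop_config_error")
})

test_that("weather generation is seeded-deterministic and physically sane", {
  cfg <- small_config()
  w1 <- simulate_weather(cfg, "C001", 2003)
  w2 <- simulate_weather(cfg, "C001", 2003)
  expect_identical(w1, w2)
  expect_true(all(w1$tmax_c >= w1$tmin_c))
  expect_true(all(w1$precip_mm >= 0))
  expect_true(all(w1$srad_wm2 >= 0))
  expect_true(all(w1$vpd_kpa >= 0))
  expect_true(all(w1$pdsi >= -6 & w1$pdsi <= 6))
  expect_error(simulate_weather(cfg, "C001", 1990),
               class = "primecrop_input_error")
  expect_error(simulate_weather(cfg, "nope", 2003),
               class = "primecrop_input_error")
})

test_that("zero-noise weather reproduces the seasonal climatology exactly", {
  cfg <- small_config(weather_climatology = list(
    tmax_sd = 0, county_tmax_sd = 0, diurnal_range_sd = 0))
  w <- simulate_weather(cfg, "C002", 2004)
  clim <- cfg$weather_climatology
  s <- 0.5 * (1 + cos(2 * pi * (w$doy - 196) / 365))
  expect_equal(w$tmax_c,
               clim$tmax_winter + (clim$tmax_summer - clim$tmax_winter) * s)
})

test_that("scaling late-season precipitation to zero depresses the drought proxy", {
  cfg <- small_config()
  base <- simulate_weather(cfg, "C003", 2005)
  dr <- simulate_weather(cfg, "C003", 2005,
                         precip_windows = data.frame(start_doy = 205,
                                                     end_doy = 265,
                                                     factor = 0))
  late <- base$doy >= 240 & base$doy < 265
  expect_lt(mean(dr$pdsi[late]), mean(base$pdsi[late]))
  expect_lt(mean(dr$pdsi[late]), -2)
})

test_that("noise-free reflectance round-trips through the vegetation index", {
  cfg <- noiseless_config()
  stages <- c(150, 200, 240, 265)
  rf <- simulate_reflectance(stages, cfg, pixel = "PX", year = 2001)
  w <- compute_wdrvi(rf, cfg$alpha)
  expect_equal(w$wdrvi, canopy_curve(w$doy, stages, cfg), tolerance = 1e-12)
})

test_that("winter composites sit at the bare-soil baseline below the emergence threshold", {
  cfg <- noiseless_config()
  rf <- simulate_reflectance(c(150, 200, 240, 265), cfg, "PX", 2001)
  w <- compute_wdrvi(rf, cfg$alpha)
  winter <- w$doy < 100 | w$doy > 330
  expect_true(all(w$wdrvi[winter] < -0.68))
})

test_that("bad-composite counts follow the configured missing rate", {
  total <- 0
  for (s in 1:100) {
    cfg <- simulation_config(seed = s, n_counties = 1, years = 2000,
                             pixels_per_county = 1, missing_rate = 0.2)
    rf <- simulate_reflectance(c(150, 200, 240, 265), cfg, "PX", 2000)
    total <- total + sum(rf$qc_flag == "bad")
  }
  n <- 100 * 46
  half <- stats::qnorm(0.995) * sqrt(n * 0.2 * 0.8)
  expect_gt(total, n * 0.2 - half)
  expect_lt(total, n * 0.2 + half)
})

test_that("yield construction embeds the drought loss and mitigation exactly", {
  run_yields <- function(loss, mitig) {
    cfg <- noiseless_config(drought_loss = loss,
                            priming_mitigation_frac = mitig)
    sc <- make_scenario(cfg)
    y <- sc$yields
    lab <- sc$truth$labels$label
    gm <- tapply(y$yield_mg_ha, lab, mean)
    gm
  }
  gm <- run_yields(1.0, 0)
  expect_equal(unname(gm["priming"] - gm["nonpriming"]), 0)
  expect_equal(unname(gm["control"] - gm["nonpriming"]), 1.0)
  gm2 <- run_yields(0.55, 0.673)
  expect_equal(unname(gm2["priming"] - gm2["nonpriming"]), 0.55 * 0.673)
  expect_equal(round(unname(gm2["priming"] - gm2["nonpriming"]), 2), 0.37)
})

test_that("oversized effect sizes are rejected rather than producing negative yields", {
  cfg <- noiseless_config(drought_loss = 50)
  expect_error(make_scenario(cfg), class = "primecrop_config_error")
})

test_that("scenario bundle is consistent with its configured truth", {
  cfg <- small_config(seed = 21)
  sc <- make_scenario(cfg)
  expect_s3_class(sc, "primecrop_scenario")
  lab <- sc$truth$labels
  # every county-year labelled exactly once
  expect_equal(nrow(lab), cfg$n_counties * length(cfg$years))
  expect_false(any(duplicated(paste(lab$county_id, lab$year))))
  # mitigation injected only for priming county-years
  comp <- sc$truth$yield_components
  expect_true(all(comp$mitigation[lab$label != "priming"] == 0))
  expect_true(all(comp$mitigation[lab$label == "priming"] > 0))
  # label tallies near the configured proportions
  n <- nrow(lab)
  for (g in names(cfg$group_probs)) {
    p <- cfg$group_probs[[g]]
    expect_lt(abs(sum(lab$label == g) - n * p), 4 * sqrt(n * p * (1 - p)) + 1)
  }
  # weekly progress ratios nondecreasing within year and stage
  for (key in split(sc$cpr, paste(sc$cpr$year, sc$cpr$stage))[1:8]) {
    expect_true(all(diff(key$area_ratio[order(key$week_doy)]) >= 0))
  }
  # regeneration from the same config is byte-identical
  sc2 <- make_scenario(cfg)
  expect_identical(sc$yields, sc2$yields)
  expect_identical(sc$reflectance, sc2$reflectance)
  expect_identical(sc$weather$pdsi, sc2$weather$pdsi)
})
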