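# Seeded synthetic data generator: pixels, counties, daily weather and
# county-year yields with known ground truth (stage dates, group membership,
# injected effect sizes), so every downstream stage of the priming analysis is
# testable without any satellite or survey download.

#' Crop reference stage dates and detection thresholds
#'
#' Reference day-of-year values for the four phenological stages used by the
#' shape model (maize: emergence, silking, dent, maturity; soybean: emergence,
#' beginning seed, full seed, beginning maturity), together with the
#' vegetation-index thresholds used to detect emergence (rising) and
#' maturity (falling).
#'
#' @param crop `"maize"` or `"soybean"`.
#' @return A list with `reference_dates` (4 DOYs), `up_threshold` and
#'   `down_threshold` (scaled WDRVI units).
#' @export
crop_defaults <- function(crop = c("maize", "soybean")) {
  crop <- match.arg(crop)
  if (crop == "maize") {
    list(crop = crop,
         reference_dates = c(150, 200, 240, 265),
         stage_names = c("emergence", "silking", "dent", "maturity"),
         up_threshold = -0.68, down_threshold = -0.68)
  } else {
    list(crop = crop,
         reference_dates = c(170, 225, 240, 270),
         stage_names = c("emergence", "beginning_seed", "full_seed",
                         "beginning_maturity"),
         up_threshold = -0.68, down_threshold = -0.55)
  }
}

#' Simulation configuration
#'
#' Builds and validates the configuration that drives the whole synthetic
#' scenario: county/pixel layout, canopy phenology variability, compositing
#' noise, weather climatology, the yield model (county intercepts, technology
#' trend, per-duration weather sensitivities, drought loss) and the injected
#' priming mitigation fraction.
#'
#' @param seed integer; master seed. All randomness flows from it through
#'   named substreams, so e.g. adding pixels does not change weather draws.
#' @param n_counties,years,pixels_per_county scenario layout.
#' @param crop `"maize"` or `"soybean"`.
#' @param stage_date_means 4 increasing DOYs for the true mean stage dates.
#' @param stage_date_sd per-pixel stage-date shift SD (days).
#' @param year_shift_sd,stage_scale_sd county-year level shift SD (days) and
#'   time-scale SD (dimensionless) of the affine stage-date perturbation.
#' @param composite_noise_sd additive WDRVI noise SD per 8-day composite.
#' @param missing_rate fraction of composites flagged bad, in [0, 1).
#' @param weather_climatology named list of climatology parameters; see
#'   Details of the package vignette. Missing entries fall back to defaults.
#' @param trend_slope technology trend, Mg/Ha per year.
#' @param county_intercept_sd SD of county yield intercepts (Mg/Ha).
#' @param base_yield state-mean yield level (Mg/Ha).
#' @param weather_sensitivities named list (`tmax`, `tmin`, `srad`, `vpd`,
#'   `precip`), each a length-3 numeric of per-duration yield sensitivities
#'   applied to centered covariates.
#' @param drought_loss yield loss (Mg/Ha) for county-years with a late-season
#'   (D3) drought.
#' @param priming_mitigation_frac fraction of `drought_loss` recovered when
#'   the county-year also experienced an early (D1) drought, in [0, 1].
#' @param yield_noise_sd residual yield noise SD (Mg/Ha).
#' @param group_probs named probabilities for
#'   control/nonpriming/priming/other county-year labels.
#' @param drought_factor multiplier applied to precipitation inside forced
#'   drought windows (0 = no rain at all).
#' @param stress_type `"drought"` (precipitation scaling) or `"heat"`
#'   (temperature offset) forcing for the stress windows.
#' @param heat_delta temperature offset (deg C) for `stress_type = "heat"`.
#' @param pdsi_window,pdsi_scale trailing window (days) and scale (mm) of the
#'   standardized running water-balance drought proxy.
#' @param lai_priming_d2_shift additive LAI shift for priming county-years in
#'   duration D2 (emulates the canopy difference seen for primed crops).
#' @return A validated list of class `primecrop_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_counties = 30L,
                              years = 2000:2018,
                              pixels_per_county = 3L,
                              crop = c("maize", "soybean"),
                              stage_date_means = NULL,
                              stage_date_sd = 2,
                              year_shift_sd = 3,
                              stage_scale_sd = 0.03,
                              composite_noise_sd = 0.02,
                              missing_rate = 0.05,
                              weather_climatology = list(),
                              trend_slope = 0.1,
                              county_intercept_sd = 0.8,
                              base_yield = NULL,
                              weather_sensitivities = NULL,
                              drought_loss = 1.0,
                              priming_mitigation_frac = 0.5,
                              yield_noise_sd = 0.3,
                              group_probs = c(control = 0.3, nonpriming = 0.3,
                                              priming = 0.3, other = 0.1),
                              drought_factor = 0.05,
                              stress_type = c("drought", "heat"),
                              heat_delta = 1.2,
                              pdsi_window = 25L,
                              pdsi_scale = 21,
                              lai_priming_d2_shift = NULL) {
  crop <- match.arg(crop)
  stress_type <- match.arg(stress_type)
  defs <- crop_defaults(crop)
  stage_date_means <- stage_date_means %||% defs$reference_dates
  base_yield <- base_yield %||% if (crop == "maize") 9.8 else 3.4
  weather_sensitivities <- weather_sensitivities %||% list(
    tmax = c(0, -0.01, -0.03), tmin = c(0, 0, 0),
    srad = c(0.001, 0.001, 0), vpd = c(0, -0.1, -0.2),
    precip = c(0, 0, 0))
  lai_priming_d2_shift <-
    lai_priming_d2_shift %||% if (crop == "maize") 0.3 else -0.2

  clim_defaults <- list(
    tmax_summer = 30, tmax_winter = 0, tmax_sd = 3,
    diurnal_range = 10, diurnal_range_sd = 1.5,
    precip_prob = 0.5, precip_mean_mm = 6, precip_seasonal_amp = 0.2,
    srad_summer = 260, srad_winter = 90, srad_sd = 25,
    vpd_summer = 1.2, vpd_winter = 0.3, vpd_sd = 0.15,
    county_tmax_sd = 0.7, county_precip_sd = 0.08,
    demand_coef = 0.25)
  clim <- utils::modifyList(clim_defaults, weather_climatology)

  sds <- c(stage_date_sd = stage_date_sd, year_shift_sd = year_shift_sd,
           stage_scale_sd = stage_scale_sd,
           composite_noise_sd = composite_noise_sd,
           county_intercept_sd = county_intercept_sd,
           yield_noise_sd = yield_noise_sd)
  if (any(sds < 0))
    stop_primecrop(paste("negative SD:", paste(names(sds)[sds < 0],
                                               collapse = ", ")),
                   "primecrop_config_error")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_primecrop("missing_rate must be in [0, 1)", "primecrop_config_error")
  if (length(stage_date_means) != 4 || any(diff(stage_date_means) <= 0))
    stop_primecrop("stage_date_means must be 4 strictly increasing DOYs",
                   "primecrop_config_error")
  if (priming_mitigation_frac < 0 || priming_mitigation_frac > 1)
    stop_primecrop("priming_mitigation_frac must be in [0, 1]",
                   "primecrop_config_error")
  if (drought_factor < 0 || drought_factor > 1)
    stop_primecrop("drought_factor must be in [0, 1]",
                   "primecrop_config_error")
  stopifnot(n_counties >= 1, pixels_per_county >= 1, length(years) >= 1)
  gp <- group_probs[c("control", "nonpriming", "priming", "other")]
  if (anyNA(gp) || any(gp < 0) || sum(gp) <= 0)
    stop_primecrop("group_probs needs nonnegative control/nonpriming/priming/other",
                   "primecrop_config_error")
  gp <- gp / sum(gp)

  structure(list(
    seed = as.integer(seed), n_counties = as.integer(n_counties),
    years = as.integer(years), pixels_per_county = as.integer(pixels_per_county),
    crop = crop, stage_date_means = stage_date_means,
    stage_names = defs$stage_names,
    up_threshold = defs$up_threshold, down_threshold = defs$down_threshold,
    stage_date_sd = stage_date_sd, year_shift_sd = year_shift_sd,
    stage_scale_sd = stage_scale_sd,
    composite_noise_sd = composite_noise_sd, missing_rate = missing_rate,
    weather_climatology = clim,
    trend_slope = trend_slope, county_intercept_sd = county_intercept_sd,
    base_yield = base_yield, weather_sensitivities = weather_sensitivities,
    drought_loss = drought_loss,
    priming_mitigation_frac = priming_mitigation_frac,
    yield_noise_sd = yield_noise_sd, group_probs = gp,
    drought_factor = drought_factor, stress_type = stress_type,
    heat_delta = heat_delta,
    pdsi_window = as.integer(pdsi_window), pdsi_scale = pdsi_scale,
    lai_priming_d2_shift = lai_priming_d2_shift,
    wdrvi_min = -0.85, wdrvi_max = 0.08, alpha = 0.1
  ), class = "primecrop_config")
}

county_ids <- function(config) sprintf("C%03d", seq_len(config$n_counties))

pixel_ids <- function(config, county) {
  sprintf("%s_P%02d", county, seq_len(config$pixels_per_county))
}

# Smooth seasonal weight in [0, 1], peaking at `peak_doy`.
seasonal_weight <- function(doy, peak_doy = 196) {
  0.5 * (1 + cos(2 * pi * (doy - peak_doy) / 365))
}

# Seasonal precipitation factor: wetter springs, drier late summers.
precip_seasonal <- function(doy, amp) 1 + amp * cos(2 * pi * (doy - 120) / 365)

county_effects <- function(config, county) {
  clim <- config$weather_climatology
  with_seed(substream_seed(config$seed, "county", county), {
    list(tmax_offset = stats::rnorm(1, 0, clim$county_tmax_sd),
         precip_mult = exp(stats::rnorm(1, 0, clim$county_precip_sd)))
  })
}

window_factor <- function(doy, windows, default = 1) {
  f <- rep(default, length(doy))
  if (is.null(windows) || nrow(windows) == 0) return(f)
  for (k in seq_len(nrow(windows))) {
    sel <- doy >= windows$start_doy[k] & doy <= windows$end_doy[k]
    f[sel] <- f[sel] * windows$factor[k]
  }
  f
}

#' Simulate one county-year of daily weather
#'
#' Generates daily maximum/minimum temperature, precipitation, shortwave
#' radiation and VPD from a smooth seasonal climatology with county offsets,
#' and computes a drought-index proxy: the standardized trailing water balance
#' (precipitation minus temperature-scaled demand over `pdsi_window` days,
#' standardized against the county's noise-free expectation and clipped to
#' [-6, 6]). Optional windows force drought (precipitation scaling) or heat
#' (temperature offsets) inside chosen day ranges; this is how the scenario
#' generator creates early/late-season stress with known truth.
#'
#' @param config a [simulation_config()].
#' @param county,year county id (as from the scenario) and calendar year.
#' @param precip_windows optional data.frame (`start_doy`, `end_doy`,
#'   `factor`) multiplying precipitation inside the windows.
#' @param tmax_offset_windows optional data.frame (`start_doy`, `end_doy`,
#'   `delta`) adding `delta` deg C to Tmax/Tmin inside the windows.
#' @return data.frame, one row per day of year 1..365: `county_id`, `date`,
#'   `year`, `doy`, `tmax_c`, `tmin_c`, `precip_mm`, `srad_wm2`, `vpd_kpa`,
#'   `pdsi`.
#' @export
simulate_weather <- function(config, county, year,
                             precip_windows = NULL,
                             tmax_offset_windows = NULL) {
  if (!year %in% config$years)
    stop_primecrop(sprintf("unknown year %s", year), "primecrop_input_error")
  if (!county %in% county_ids(config))
    stop_primecrop(sprintf("unknown county %s", county),
                   "primecrop_input_error")
  clim <- config$weather_climatology
  eff <- county_effects(config, county)
  doy <- 1:365
  s <- seasonal_weight(doy)
  tmax_clim <- clim$tmax_winter + (clim$tmax_summer - clim$tmax_winter) * s
  heat_add <- if (is.null(tmax_offset_windows)) rep(0, 365) else {
    add <- rep(0, 365)
    for (k in seq_len(nrow(tmax_offset_windows))) {
      sel <- doy >= tmax_offset_windows$start_doy[k] &
        doy <= tmax_offset_windows$end_doy[k]
      add[sel] <- add[sel] + tmax_offset_windows$delta[k]
    }
    add
  }

  with_seed(substream_seed(config$seed, "weather", county, year), {
    tmax <- tmax_clim + eff$tmax_offset + heat_add +
      stats::rnorm(365, 0, clim$tmax_sd)
    rng <- pmax(2, stats::rnorm(365, clim$diurnal_range,
                                clim$diurnal_range_sd))
    tmin <- tmax - rng
    srad <- pmax(0, clim$srad_winter +
                   (clim$srad_summer - clim$srad_winter) * s +
                   stats::rnorm(365, 0, clim$srad_sd))
    vpd <- pmax(0, clim$vpd_winter + (clim$vpd_summer - clim$vpd_winter) * s +
                  stats::rnorm(365, 0, clim$vpd_sd))
    wet <- stats::runif(365) < clim$precip_prob
    # gamma-shaped wet-day amounts: right-skewed but less variable than
    # exponential, so forced droughts separate cleanly from dry spells
    amounts <- stats::rgamma(365, shape = 2, scale = clim$precip_mean_mm / 2)
    pf <- precip_seasonal(doy, clim$precip_seasonal_amp) * eff$precip_mult *
      window_factor(doy, precip_windows)
    precip <- ifelse(wet, amounts * pf, 0)
    list(tmax = tmax, tmin = tmin, srad = srad, vpd = vpd, precip = precip)
  }) -> w

  # Drought proxy: trailing water balance standardized against the noise-free
  # climatological expectation (drought windows excluded from the reference).
  demand <- clim$demand_coef * pmax(w$tmax, 0)
  exp_precip <- clim$precip_prob * clim$precip_mean_mm *
    precip_seasonal(doy, clim$precip_seasonal_amp) * eff$precip_mult
  exp_demand <- clim$demand_coef *
    pmax(tmax_clim + eff$tmax_offset, 0)
  wb <- w$precip - demand
  wb_ref <- exp_precip - exp_demand
  roll <- function(x, n) {
    cs <- cumsum(x)
    cs - c(rep(0, n), utils::head(cs, -n))
  }
  n <- config$pdsi_window
  pdsi <- clip((roll(wb, n) - roll(wb_ref, n)) / config$pdsi_scale, -6, 6)

  data.frame(
    county_id = county,
    date = as.Date(doy - 1, origin = paste0(year, "-01-01")),
    year = year, doy = doy,
    tmax_c = w$tmax, tmin_c = w$tmin, precip_mm = w$precip,
    srad_wm2 = w$srad, vpd_kpa = w$vpd, pdsi = pdsi,
    stringsAsFactors = FALSE)
}

#' Idealized seasonal canopy curve anchored at stage dates
#'
#' Double-logistic scaled-WDRVI curve whose rising limb crosses the emergence
#' threshold at stage 1 and whose falling limb crosses the maturity threshold
#' at stage 4. All time parameters (inflection points, rise/fall widths) are
#' affine combinations of the stage dates, so a shift-and-scale perturbation
#' of the stage dates yields an exact time-affine transform of the curve —
#' the transformation family the shape-model fit estimates.
#'
#' @param doy numeric vector of days of year.
#' @param stage_dates 4 increasing DOYs.
#' @param config a [simulation_config()] (supplies thresholds and the WDRVI
#'   floor/ceiling).
#' @return numeric vector of scaled WDRVI values.
#' @export
canopy_curve <- function(doy, stage_dates, config) {
  if (any(diff(stage_dates) <= 0))
    stop_primecrop("stage dates must be strictly increasing",
                   "primecrop_input_error")
  wmin <- config$wdrvi_min; wmax <- config$wdrvi_max
  s1 <- stage_dates[1]; s2 <- stage_dates[2]
  s3 <- stage_dates[3]; s4 <- stage_dates[4]
  r1 <- (s2 - s1) / 8
  r2 <- (s4 - s3) / 6
  p1 <- (config$up_threshold - wmin) / (wmax - wmin)
  p2 <- (config$down_threshold - wmin) / (wmax - wmin)
  t1 <- s1 - r1 * log(p1 / (1 - p1))
  t2 <- s4 + r2 * log(p2 / (1 - p2))
  sig_up <- 1 / (1 + exp(-(doy - t1) / r1))
  sig_down <- 1 / (1 + exp((doy - t2) / r2))
  wmin + (wmax - wmin) * (sig_up + sig_down - 1)
}

#' Simulate one pixel-year of two-band 8-day composites
#'
#' Inverts the vegetation index: band reflectances are constructed so that the
#' exact index value equals the idealized canopy curve (anchored at the true
#' stage dates) plus additive compositing noise. A fraction of composites is
#' flagged bad and given corrupted values (bad composites are flagged, not
#' dropped, mirroring quality-flag filtering upstream of index computation).
#'
#' @param true_stage_dates 4 increasing DOYs for this pixel-year.
#' @param config a [simulation_config()].
#' @param pixel,year optional identifiers; they key the noise substream so
#'   regeneration is reproducible per pixel-year.
#' @return data.frame (`pixel_id`, `year`, `doy`, `ref_b1`, `ref_b2`,
#'   `qc_flag`) with 46 composites at 8-day spacing.
#' @export
simulate_reflectance <- function(true_stage_dates, config,
                                 pixel = "P00", year = 0L) {
  doy <- seq(1, 361, by = 8)
  w_true <- canopy_curve(doy, true_stage_dates, config)
  with_seed(substream_seed(config$seed, "reflectance", pixel, year), {
    w <- w_true + stats::rnorm(length(doy), 0, config$composite_noise_sd)
    bad <- stats::runif(length(doy)) < config$missing_rate
    # bad composites carry cloud/snow-contaminated values
    w[bad] <- w[bad] + stats::runif(sum(bad), -0.5, 0.5)
    w <- clip(w, -0.98, 0.95)
    b2 <- clip(0.18 + 0.32 * (w_true - config$wdrvi_min) /
                 (config$wdrvi_max - config$wdrvi_min), 0.05, 1)
    b1 <- config$alpha * b2 * (1 - w) / (1 + w)
    data.frame(pixel_id = pixel, year = as.integer(year), doy = doy,
               ref_b1 = clip(b1, 0, 1), ref_b2 = b2,
               qc_flag = ifelse(bad, "bad", "good"),
               stringsAsFactors = FALSE)
  })
}

#' Simulate county-year yields with known generative structure
#'
#' Yield = county intercept + technology trend + per-duration weather terms
#' (sensitivities applied to panel-centered covariates) − drought loss for
#' county-years with a late (D3) drought + partial recovery of that loss for
#' primed county-years + Gaussian noise.
#'
#' @param config a [simulation_config()].
#' @param duration_climate data.frame with columns `county_id`, `year`,
#'   `duration` (`"D1".."D3"`), `tmax`, `tmin`, `srad`, `vpd`, `precip_total`.
#' @param truth the `SyntheticTruth` list from [make_scenario()] (or at least
#'   its `labels` data.frame with `county_id`, `year`, `label`).
#' @return data.frame (`county_id`, `year`, `crop`, `yield_mg_ha`) plus the
#'   injected components as attribute `"components"`.
#' @export
simulate_yields <- function(config, duration_climate, truth) {
  labels <- truth$labels
  key <- paste(labels$county_id, labels$year)
  wide <- stats::reshape(
    duration_climate[, c("county_id", "year", "duration", "tmax", "tmin",
                         "srad", "vpd", "precip_total")],
    direction = "wide", idvar = c("county_id", "year"),
    timevar = "duration", sep = "_")
  wkey <- paste(wide$county_id, wide$year)
  if (!all(key %in% wkey))
    stop_primecrop("duration climate missing for some labelled county-years",
                   "primecrop_input_error")
  wide <- wide[match(key, wkey), ]

  sens <- config$weather_sensitivities
  vars <- c(tmax = "tmax", tmin = "tmin", srad = "srad", vpd = "vpd",
            precip = "precip_total")
  weather_term <- rep(0, nrow(wide))
  for (v in names(vars)) {
    for (j in 1:3) {
      col <- paste0(vars[[v]], "_D", j)
      x <- wide[[col]]
      weather_term <- weather_term + sens[[v]][j] * (x - mean(x))
    }
  }

  intercepts <- with_seed(substream_seed(config$seed, "intercepts"), {
    stats::setNames(stats::rnorm(config$n_counties, 0,
                                 config$county_intercept_sd),
                    county_ids(config))
  })
  noise <- with_seed(substream_seed(config$seed, "yield_noise"), {
    stats::rnorm(nrow(labels), 0, config$yield_noise_sd)
  })

  d3_drought <- labels$label %in% c("nonpriming", "priming")
  trend <- config$trend_slope * (labels$year - min(config$years))
  loss <- -config$drought_loss * d3_drought
  mitig <- config$drought_loss * config$priming_mitigation_frac *
    (labels$label == "priming")
  yield <- config$base_yield + intercepts[labels$county_id] + trend +
    weather_term + loss + mitig + noise
  if (any(yield <= 0))
    stop_primecrop("configured effect sizes produce non-positive yields",
                   "primecrop_config_error")
  out <- data.frame(county_id = labels$county_id, year = labels$year,
                    crop = config$crop, yield_mg_ha = as.numeric(yield),
                    stringsAsFactors = FALSE)
  attr(out, "components") <- data.frame(
    county_id = labels$county_id, year = labels$year,
    trend = trend, weather = weather_term, drought_loss = loss,
    mitigation = mitig, noise = noise)
  out
}

# Stress windows (DOY ranges) for a county-year given its label and the
# county-year mean true stage dates. The drought proxy is a trailing water
# balance, so a window must lead its target duration to register there; the
# early window ends before stage 2 so the proxy decays back toward normal
# inside D2, and the late window's lead is capped so it does not reach far
# into D2 (D2 can be short, e.g. for soybean).
stress_windows <- function(label, stages, config) {
  lead <- config$pdsi_window
  late_lead <- max(10, min(lead, (stages[3] - stages[2]) - 15))
  w <- NULL
  if (label %in% c("priming")) {
    w <- rbind(w, data.frame(start_doy = stages[1] - lead,
                             end_doy = stages[2] - 15))
  }
  if (label %in% c("priming", "nonpriming")) {
    w <- rbind(w, data.frame(start_doy = stages[3] - late_lead,
                             end_doy = stages[4]))
  }
  if (label == "other") {
    w <- rbind(w, data.frame(start_doy = stages[2] - 10,
                             end_doy = stages[3]))
  }
  w
}

#' Generate a complete synthetic scenario with ground truth
#'
#' Draws county-year group labels (control / nonpriming / priming / other),
#' builds affine-perturbed true stage dates per pixel-year, simulates weather
#' with stress windows matching each label, two-band composites, a crop
#' fraction table, weekly crop-progress area ratios, a county LAI table and
#' county-year yields embedding the configured drought loss and priming
#' mitigation.
#'
#' @param config a [simulation_config()].
#' @return list of class `primecrop_scenario` with elements `reflectance`,
#'   `weather`, `yields`, `cdl`, `cpr`, `lai`, `duration_climate_true`
#'   (aggregates over the true stage windows) and `truth` (labels, true pixel
#'   and county stage dates, injected yield components).
#' @export
make_scenario <- function(config) {
  counties <- county_ids(config)
  years <- config$years
  ref <- config$stage_date_means
  pivot <- mean(ref)

  grid <- expand.grid(county_id = counties, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$county_id, grid$year), ]
  labels <- with_seed(substream_seed(config$seed, "labels"), {
    sample(names(config$group_probs), nrow(grid), replace = TRUE,
           prob = config$group_probs)
  })
  labels_df <- data.frame(grid, label = labels, stringsAsFactors = FALSE)

  # county-year affine stage transforms, then pixel-level jitter (also affine)
  cy <- with_seed(substream_seed(config$seed, "stage_transforms"), {
    data.frame(grid,
               shift = stats::rnorm(nrow(grid), 0, config$year_shift_sd),
               scale = pmax(0.85, stats::rnorm(nrow(grid), 1,
                                               config$stage_scale_sd)))
  })

  refl <- vector("list", nrow(grid) * config$pixels_per_county)
  pix_truth <- vector("list", length(refl))
  idx <- 0
  county_stage <- matrix(NA_real_, nrow(grid), 4)
  for (r in seq_len(nrow(grid))) {
    cty <- grid$county_id[r]; yr <- grid$year[r]
    pxs <- pixel_ids(config, cty)
    pj <- with_seed(substream_seed(config$seed, "pixel_jitter", cty, yr), {
      data.frame(shift = stats::rnorm(length(pxs), 0, config$stage_date_sd),
                 scale = pmax(0.9, stats::rnorm(length(pxs), 1,
                                                config$stage_scale_sd / 2)))
    })
    stages_px <- lapply(seq_along(pxs), function(i) {
      sc <- cy$scale[r] * pj$scale[i]
      sh <- cy$shift[r] + pj$shift[i]
      pivot + sc * (ref - pivot) + sh
    })
    county_stage[r, ] <- colMeans(do.call(rbind, stages_px))
    for (i in seq_along(pxs)) {
      idx <- idx + 1
      rf <- simulate_reflectance(stages_px[[i]], config, pixel = pxs[i],
                                 year = yr)
      rf$county_id <- cty
      refl[[idx]] <- rf
      pix_truth[[idx]] <- data.frame(
        pixel_id = pxs[i], county_id = cty, year = yr,
        s1 = stages_px[[i]][1], s2 = stages_px[[i]][2],
        s3 = stages_px[[i]][3], s4 = stages_px[[i]][4],
        stringsAsFactors = FALSE)
    }
  }
  reflectance <- do.call(rbind, refl)
  pixel_truth <- do.call(rbind, pix_truth)
  county_truth <- data.frame(grid,
                             s1 = county_stage[, 1], s2 = county_stage[, 2],
                             s3 = county_stage[, 3], s4 = county_stage[, 4])

  weather <- do.call(rbind, lapply(seq_len(nrow(grid)), function(r) {
    lbl <- labels_df$label[r]
    st <- county_stage[r, ]
    win <- stress_windows(lbl, st, config)
    if (config$stress_type == "drought") {
      pw <- if (is.null(win)) NULL else cbind(win, factor = config$drought_factor)
      simulate_weather(config, grid$county_id[r], grid$year[r],
                       precip_windows = pw)
    } else {
      tw <- if (is.null(win)) NULL else cbind(win, delta = config$heat_delta)
      simulate_weather(config, grid$county_id[r], grid$year[r],
                       tmax_offset_windows = tw)
    }
  }))

  cdl <- with_seed(substream_seed(config$seed, "cdl"), {
    px <- unique(pixel_truth[, c("pixel_id", "county_id")])
    do.call(rbind, lapply(years, function(yr) {
      mixed <- stats::runif(nrow(px)) < 0.1
      frac <- ifelse(mixed, stats::runif(nrow(px), 0.3, 0.79),
                     stats::runif(nrow(px), 0.82, 0.98))
      data.frame(pixel_id = px$pixel_id, year = yr, crop_fraction = frac,
                 stringsAsFactors = FALSE)
    }))
  })

  # weekly crop-progress area ratios from the state-mean true stage dates
  cpr <- do.call(rbind, lapply(years, function(yr) {
    sel <- county_truth$year == yr
    mu <- colMeans(county_truth[sel, c("s1", "s2", "s3", "s4")])
    do.call(rbind, lapply(1:4, function(k) {
      wk <- seq(110, 320, by = 7)
      data.frame(state_id = "S01", year = yr, stage = paste0("S", k),
                 week_doy = wk,
                 area_ratio = 100 * stats::plogis((wk - mu[k]) / 3.5),
                 stringsAsFactors = FALSE)
    }))
  }))

  # duration climate over the TRUE stage windows (generative input to yields)
  duration_climate_true <- do.call(rbind, lapply(seq_len(nrow(grid)), function(r) {
    rec <- list(county_id = grid$county_id[r], year = grid$year[r],
                crop = config$crop,
                s1 = round_half_up(county_stage[r, 1]),
                s2 = round_half_up(county_stage[r, 2]),
                s3 = round_half_up(county_stage[r, 3]),
                s4 = round_half_up(county_stage[r, 4]))
    aggregate_duration(weather[weather$county_id == grid$county_id[r] &
                                 weather$year == grid$year[r], ], rec)
  }))

  truth <- list(labels = labels_df, pixel_stage_dates = pixel_truth,
                county_stage_dates = county_truth)
  yields <- simulate_yields(config, duration_climate_true, truth)
  truth$yield_components <- attr(yields, "components")

  lai <- with_seed(substream_seed(config$seed, "lai"), {
    base <- c(D1 = 1.6, D2 = 5.0, D3 = 3.4)
    if (config$crop == "soybean") base <- c(D1 = 1.2, D2 = 4.2, D3 = 3.0)
    do.call(rbind, lapply(c("D1", "D2", "D3"), function(d) {
      shift <- ifelse(d == "D2" & labels_df$label == "priming",
                      config$lai_priming_d2_shift, 0)
      data.frame(county_id = grid$county_id, year = grid$year, duration = d,
                 lai = pmax(0, base[[d]] + shift +
                              stats::rnorm(nrow(grid), 0, 0.25)),
                 stringsAsFactors = FALSE)
    }))
  })

  structure(list(config = config, reflectance = reflectance,
                 weather = weather, yields = yields, cdl = cdl, cpr = cpr,
                 lai = lai, duration_climate_true = duration_climate_true,
                 truth = truth),
            class = "primecrop_scenario")
}

#' Write a scenario's tables to delimited text files
#'
#' @param scenario a `primecrop_scenario` from [make_scenario()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of file paths written.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    reflectance = file.path(dir, "reflectance.csv"),
    weather = file.path(dir, "weather.csv"),
    yields = file.path(dir, "yields.csv"),
    cdl = file.path(dir, "cdl.csv"),
    cpr = file.path(dir, "cpr.csv"),
    lai = file.path(dir, "lai.csv"))
  utils::write.csv(scenario$reflectance[, c("pixel_id", "county_id", "year",
                                            "doy", "ref_b1", "ref_b2",
                                            "qc_flag")],
                   paths["reflectance"], row.names = FALSE)
  utils::write.csv(scenario$weather, paths["weather"], row.names = FALSE)
  utils::write.csv(scenario$yields, paths["yields"], row.names = FALSE)
  utils::write.csv(scenario$cdl, paths["cdl"], row.names = FALSE)
  utils::write.csv(scenario$cpr, paths["cpr"], row.names = FALSE)
  utils::write.csv(scenario$lai, paths["lai"], row.names = FALSE)
  jsonlite::write_json(scenario$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(c(paths, truth = file.path(dir, "truth.json")))
}
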