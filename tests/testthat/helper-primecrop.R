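# Shared fixtures, built in code.

# Small scenario configuration for fast tests.
small_config <- function(seed = 11, ...) {
  simulation_config(seed = seed, n_counties = 8, years = 2000:2009,
                    pixels_per_county = 2, ...)
}

# Deterministic generator configuration (no stochastic components).
noiseless_config <- function(seed = 5, ...) {
  simulation_config(
    seed = seed, n_counties = 4, years = 2000:2006, pixels_per_county = 1,
    stage_date_sd = 0, year_shift_sd = 0, stage_scale_sd = 0,
    composite_noise_sd = 0, missing_rate = 0,
    trend_slope = 0, county_intercept_sd = 0, yield_noise_sd = 0,
    weather_sensitivities = list(tmax = rep(0, 3), tmin = rep(0, 3),
                                 srad = rep(0, 3), vpd = rep(0, 3),
                                 precip = rep(0, 3)),
    ...)
}

as_wdrvi_series <- function(doy, wdrvi, year = 1L) {
  structure(list(doy = doy, wdrvi = wdrvi, year = year),
            class = "wdrvi_series")
}

# Independent linear-scan oracles for the classification bins, written
# directly from the printed category lists.
oracle_pdsi <- function(v) {
  if (v <= -4) "Extreme Drought"
  else if (v <= -3) "Severe Drought"
  else if (v <= -2) "Moderate Drought"
  else if (v < 2) "Near Normal"
  else if (v < 3) "Unusual Moist Spell"
  else if (v < 4) "Very Moist Spell"
  else "Extremely Moist"
}

oracle_spa <- function(v) {
  if (v <= -2) "Extreme Dry"
  else if (v <= -0.5) "Moderate Dry"
  else if (v < 0.5) "Near Normal"
  else if (v < 2.5) "Moderate Wet"
  else "Extreme Wet"
}

oracle_sta <- function(v) {
  if (v <= -2) "Extreme Cold"
  else if (v <= -0.5) "Moderate Cold"
  else if (v < 0.5) "Near Normal"
  else if (v < 2.5) "Moderate Heat"
  else "Extreme Heat"
}

# Truth-table oracle for group assignment from three duration values.
oracle_group <- function(v1, v2, v3, rules) {
  inw <- function(x, w) x > w[1] & x < w[2]
  for (g in c("priming", "nonpriming", "control")) {
    w <- rules[[g]]
    if (inw(v1, w$d1) && inw(v2, w$d2) && inw(v3, w$d3)) return(g)
  }
  "excluded"
}

# Generative panel with known coefficients for the fixed-effects models.
make_test_panel <- function(n_counties = 20, n_years = 10, seed = 1,
                            noise_sd = 0, trend = 0.1,
                            coefs = NULL, vars = c("tmax", "tmin", "srad",
                                                   "vpd")) {
  set.seed(seed)
  cols <- as.vector(outer(vars, c("D1", "D2", "D3"), paste, sep = "_"))
  if (is.null(coefs)) coefs <- stats::setNames(
    round(stats::runif(length(cols), -0.3, 0.3), 3), cols)
  counties <- sprintf("C%02d", seq_len(n_counties))
  years <- 2000:(2000 + n_years - 1)
  panel <- expand.grid(county_id = counties, year = years,
                       stringsAsFactors = FALSE)
  intercepts <- stats::setNames(stats::rnorm(n_counties, 9, 0.8), counties)
  for (cc in cols) panel[[cc]] <- stats::rnorm(nrow(panel))
  # always carry a precipitation column so the heat-variant model can run
  for (j in 1:3) {
    cc <- paste0("precip_total_D", j)
    if (!cc %in% names(panel)) panel[[cc]] <- stats::rnorm(nrow(panel))
  }
  X <- as.matrix(panel[, cols])
  panel$yield_mg_ha <- intercepts[panel$county_id] +
    trend * (panel$year - min(panel$year)) +
    drop(X %*% coefs) + stats::rnorm(nrow(panel), 0, noise_sd)
  panel$crop <- "maize"
  attr(panel, "coefs") <- coefs
  attr(panel, "trend") <- trend
  panel
}
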