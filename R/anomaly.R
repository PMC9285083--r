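# County-year yield anomalies: panel fixed-effects models removing weather-
# and trend-driven variation, leaving the drought (or heat) signal in the
# residual.

#' Assemble the panel dataset from yields and duration climate
#'
#' Pivots the duration-climate table wide (one column per variable x
#' duration) and joins it to the county-year yields.
#'
#' @param yields data.frame (`county_id`, `year`, `crop`, `yield_mg_ha`).
#' @param duration_climate long table as from [climate_table()].
#' @return data.frame keyed by (`county_id`, `year`) with `yield_mg_ha` and
#'   columns `tmax_D1` .. `precip_total_D3`.
#' @export
make_panel <- function(yields, duration_climate) {
  wide <- stats::reshape(
    duration_climate[, c("county_id", "year", "duration", "tmax", "tmin",
                         "srad", "vpd", "precip_total")],
    direction = "wide", idvar = c("county_id", "year"),
    timevar = "duration", sep = "_")
  panel <- merge(yields, wide, by = c("county_id", "year"))
  cov_cols <- setdiff(names(panel),
                      c("county_id", "year", "crop", "yield_mg_ha"))
  panel <- panel[stats::complete.cases(panel[, cov_cols]), ]
  tab <- table(panel$county_id)
  if (length(tab) < 2 || any(tab < 2))
    stop_primecrop("panel needs >= 2 counties and >= 2 years per county",
                   "primecrop_input_error")
  panel[order(panel$county_id, panel$year), ]
}

panel_covariates <- function(panel, vars) {
  cols <- as.vector(outer(vars, c("D1", "D2", "D3"), paste, sep = "_"))
  missing <- setdiff(cols, names(panel))
  if (length(missing))
    stop_primecrop(paste("panel lacks covariate columns:",
                         paste(missing, collapse = ", ")),
                   "primecrop_input_error")
  empty <- cols[vapply(cols, function(cc) all(!is.finite(panel[[cc]])),
                       logical(1))]
  if (length(empty))
    stop_primecrop(paste("empty covariate columns:",
                         paste(empty, collapse = ", ")),
                   "primecrop_input_error")
  cols
}

fit_panel_ols <- function(panel, vars, variant) {
  cols <- panel_covariates(panel, vars)
  df <- panel
  df$t <- df$year - min(df$year)
  df$county <- factor(df$county_id)
  X <- stats::model.matrix(
    stats::as.formula(paste("~ 0 + county + t +",
                            paste(cols, collapse = " + "))), df)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop_primecrop(paste("collinear design; offending columns:",
                         paste(dropped, collapse = ", ")),
                   "primecrop_collinearity_error")
  }
  fml <- stats::as.formula(paste("yield_mg_ha ~ 0 + county + t +",
                                 paste(cols, collapse = " + ")))
  m <- stats::lm(fml, data = df)
  fitted <- stats::fitted(m)
  r2 <- 1 - sum(stats::residuals(m)^2) /
    sum((df$yield_mg_ha - mean(df$yield_mg_ha))^2)
  cf <- stats::coef(m)
  structure(list(
    variant = variant, model = m,
    trend = cf[["t"]],
    weather_coefficients = cf[cols],
    county_intercepts = cf[grep("^county", names(cf))],
    fitted = data.frame(county_id = df$county_id, year = df$year,
                        fitted = as.numeric(fitted)),
    residuals = as.numeric(stats::residuals(m)),
    r2 = r2, n = nrow(df)),
    class = "panel_fit")
}

#' Fit the full-weather panel model (strategy C1)
#'
#' Ordinary least squares with a separate intercept per county, a common
#' linear year trend and 12 weather slopes: maximum temperature, minimum
#' temperature, solar radiation and VPD in each of the three phenological
#' durations. Precipitation is deliberately excluded so the drought signal
#' stays in the residual.
#'
#' @param panel data.frame from [make_panel()].
#' @return a `panel_fit`: coefficients, county intercepts, fitted values,
#'   residuals, R-squared.
#' @export
fit_panel_c1 <- function(panel) {
  fit_panel_ols(panel, c("tmax", "tmin", "srad", "vpd"), "C1")
}

#' Fit the heat-variant panel model
#'
#' As [fit_panel_c1()] but with minimum temperature, solar radiation, VPD and
#' total precipitation per duration; maximum temperature is deliberately
#' excluded so the heat signal stays in the residual.
#'
#' @param panel data.frame from [make_panel()].
#' @return a `panel_fit`.
#' @export
fit_panel_temp <- function(panel) {
  fit_panel_ols(panel, c("tmin", "srad", "vpd", "precip_total"), "Ctemp")
}

#' Fit per-county linear trends (strategy C2)
#'
#' Independent linear regression of yield on year for every county; the
#' fitted lines are the expected yields and the residuals the trend-only
#' anomalies. Counties with fewer than 3 years are excluded and counted.
#'
#' @param panel data.frame with `county_id`, `year`, `yield_mg_ha`.
#' @return list of class `trend_fit`: `coefficients` (per-county intercept
#'   and slope), `fitted` (county-year fitted values), `excluded`.
#' @export
fit_trend_c2 <- function(panel) {
  sp <- split(panel, panel$county_id)
  excluded <- character(0)
  co <- list(); ft <- list()
  for (cty in names(sp)) {
    g <- sp[[cty]]
    if (length(unique(g$year)) < 3) {
      excluded <- c(excluded, cty)
      next
    }
    m <- stats::lm(yield_mg_ha ~ I(year - min(year)), data = g)
    co[[cty]] <- data.frame(county_id = cty,
                            intercept = stats::coef(m)[[1]],
                            slope = stats::coef(m)[[2]],
                            stringsAsFactors = FALSE)
    ft[[cty]] <- data.frame(county_id = cty, year = g$year,
                            fitted = as.numeric(stats::fitted(m)),
                            stringsAsFactors = FALSE)
  }
  if (!length(co))
    stop_primecrop("no county has >= 3 years", "primecrop_input_error")
  structure(list(variant = "C2",
                 coefficients = do.call(rbind, co),
                 fitted = do.call(rbind, ft),
                 excluded = excluded),
            class = "trend_fit")
}

#' Yield anomalies: observed minus fitted
#'
#' @param panel data.frame with `county_id`, `year`, `crop`, `yield_mg_ha`.
#' @param fit a `panel_fit` or `trend_fit` covering the panel rows.
#' @param variant label stored on the records (defaults to the fit's).
#' @return data.frame (`county_id`, `year`, `crop`, `variant`,
#'   `anomaly_mg_ha`).
#' @export
compute_anomaly <- function(panel, fit, variant = fit$variant) {
  key <- paste(panel$county_id, panel$year)
  fkey <- paste(fit$fitted$county_id, fit$fitted$year)
  m <- match(key, fkey)
  if (anyNA(m)) {
    miss <- unique(panel$county_id[is.na(m)])
    stop_primecrop(paste("no fitted value for county-years in:",
                         paste(utils::head(miss, 5), collapse = ", ")),
                   "primecrop_input_error")
  }
  data.frame(county_id = panel$county_id, year = panel$year,
             crop = panel$crop, variant = variant,
             anomaly_mg_ha = panel$yield_mg_ha - fit$fitted$fitted[m],
             stringsAsFactors = FALSE)
}
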