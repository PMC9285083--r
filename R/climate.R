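# Aggregation of daily weather into the three phenological durations and
# computation/classification of drought and temperature exposure (PDSI bins,
# standardized precipitation anomaly SPA, standardized temperature anomaly
# STA).

#' Aggregate daily weather over the three phenological durations
#'
#' Temperatures, radiation, VPD and the drought index are averaged and
#' precipitation summed over the half-open windows [S1, S2), [S2, S3),
#' [S3, S4) of a county-year phenology record.
#'
#' @param weather daily table for one county-year (`doy`, `tmax_c`, `tmin_c`,
#'   `precip_mm`, `srad_wm2`, `vpd_kpa`, `pdsi`).
#' @param record list or one-row data.frame with `county_id`, `year`, `crop`,
#'   `s1`..`s4`.
#' @return 3-row data.frame (`county_id`, `year`, `crop`, `duration`, `tmax`,
#'   `tmin`, `srad`, `vpd`, `precip_total`, `pdsi`).
#' @export
aggregate_duration <- function(weather, record) {
  s <- c(record$s1, record$s2, record$s3, record$s4)
  if (any(diff(s) <= 0))
    stop_primecrop("stage dates must be strictly increasing",
                   "primecrop_input_error")
  need <- seq(s[1], s[4] - 1)
  if (!all(need %in% weather$doy))
    stop_primecrop("weather gap inside the stage window",
                   "primecrop_input_error")
  do.call(rbind, lapply(1:3, function(j) {
    sel <- weather$doy >= s[j] & weather$doy < s[j + 1]
    w <- weather[sel, ]
    data.frame(county_id = record$county_id, year = record$year,
               crop = record$crop, duration = paste0("D", j),
               tmax = mean(w$tmax_c), tmin = mean(w$tmin_c),
               srad = mean(w$srad_wm2), vpd = mean(w$vpd_kpa),
               precip_total = sum(w$precip_mm), pdsi = mean(w$pdsi),
               stringsAsFactors = FALSE)
  }))
}

standardized_anomaly <- function(panel, value_col, min_years,
                                 include_focal) {
  panel$.anom <- NA_real_
  for (g in split(seq_len(nrow(panel)),
                  paste(panel$county_id, panel$duration))) {
    x <- panel[[value_col]][g]
    if (length(x) < min_years)
      stop_primecrop(
        sprintf("fewer than %d years for %s %s", min_years,
                panel$county_id[g[1]], panel$duration[g[1]]),
        "primecrop_input_error")
    if (include_focal) {
      m <- mean(x); s <- stats::sd(x)
      if (s == 0)
        stop_primecrop(
          sprintf("zero across-year SD for %s %s",
                  panel$county_id[g[1]], panel$duration[g[1]]),
          "primecrop_undefined_error")
      panel$.anom[g] <- (x - m) / s
    } else {
      for (i in seq_along(x)) {
        xo <- x[-i]
        s <- stats::sd(xo)
        if (s == 0)
          stop_primecrop("zero leave-one-out SD",
                         "primecrop_undefined_error")
        panel$.anom[g[i]] <- (x[i] - mean(xo)) / s
      }
    }
  }
  panel$.anom
}

#' Standardized precipitation anomaly per county-year-duration
#'
#' x = (x_{y,t} - mean_t) / sd_t, where the mean and sample SD are taken
#' across years within each county x duration cell (focal year included by
#' default).
#'
#' @param panel data.frame with `county_id`, `year`, `duration`,
#'   `precip_total`.
#' @param min_years minimum years per county x duration cell.
#' @param include_focal include the focal year in its own climatology
#'   (set `FALSE` for the leave-one-out variant).
#' @return the panel with an `spa` column appended.
#' @export
compute_spa <- function(panel, min_years = 5, include_focal = TRUE) {
  panel$spa <- standardized_anomaly(panel, "precip_total", min_years,
                                    include_focal)
  panel
}

#' Standardized temperature anomaly per county-year-duration
#'
#' Same construction as [compute_spa()], applied to the duration-mean maximum
#' temperature (the heat-stress variable).
#'
#' @inheritParams compute_spa
#' @param panel data.frame with `county_id`, `year`, `duration`, `tmax`.
#' @return the panel with an `sta` column appended.
#' @export
compute_sta <- function(panel, min_years = 5, include_focal = TRUE) {
  panel$sta <- standardized_anomaly(panel, "tmax", min_years, include_focal)
  panel
}

# Bin tables. Dry-side bounds are closed on the dry side ("-4.0 or less" puts
# -4.0 in Extreme Drought); wet-side bounds are closed on the wet side
# ("+4.0 and above"). The Near Normal interval is open at both ends; together
# the bins partition the real line.
pdsi_bins <- function() {
  data.frame(
    lo = c(-Inf, -4, -3, -2, 2, 3, 4),
    hi = c(-4, -3, -2, 2, 3, 4, Inf),
    lo_open = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    hi_open = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    label = c("Extreme Drought", "Severe Drought", "Moderate Drought",
              "Near Normal", "Unusual Moist Spell", "Very Moist Spell",
              "Extremely Moist"),
    stringsAsFactors = FALSE)
}

spa_bins <- function(kind = c("precip", "temp")) {
  kind <- match.arg(kind)
  labels <- if (kind == "precip")
    c("Extreme Dry", "Moderate Dry", "Near Normal", "Moderate Wet",
      "Extreme Wet")
  else
    c("Extreme Cold", "Moderate Cold", "Near Normal", "Moderate Heat",
      "Extreme Heat")
  data.frame(
    lo = c(-Inf, -2, -0.5, 0.5, 2.5),
    hi = c(-2, -0.5, 0.5, 2.5, Inf),
    lo_open = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    hi_open = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    label = labels, stringsAsFactors = FALSE)
}

classify_bins <- function(value, bins) {
  if (any(!is.finite(value)))
    stop_primecrop("values to classify must be finite",
                   "primecrop_input_error")
  out <- character(length(value))
  for (k in seq_len(nrow(bins))) {
    lo_ok <- if (bins$lo_open[k]) value > bins$lo[k] else value >= bins$lo[k]
    hi_ok <- if (bins$hi_open[k]) value < bins$hi[k] else value <= bins$hi[k]
    out[lo_ok & hi_ok] <- bins$label[k]
  }
  out
}

#' Classify a drought-index value into its printed category
#'
#' Categories: Extreme/Severe/Moderate Drought, Near Normal, Unusual Moist
#' Spell, Very Moist Spell, Extremely Moist, with dry-side bounds closed on
#' the dry side (-4.0 itself is Extreme Drought).
#'
#' @param value finite numeric vector.
#' @return character vector of category labels.
#' @export
classify_pdsi <- function(value) classify_bins(value, pdsi_bins())

#' Classify a standardized precipitation anomaly
#'
#' Categories: Extreme Dry (x <= -2), Moderate Dry, Near Normal, Moderate
#' Wet, Extreme Wet (x >= +2.5). The bins are deliberately asymmetric: the
#' precipitation distribution has a long wet tail.
#'
#' @inheritParams classify_pdsi
#' @export
classify_spa <- function(value) classify_bins(value, spa_bins("precip"))

#' Classify a standardized temperature anomaly
#'
#' Categories: Extreme Cold (x <= -2), Moderate Cold, Near Normal, Moderate
#' Heat, Extreme Heat (x >= +2.5).
#'
#' @inheritParams classify_pdsi
#' @export
classify_sta <- function(value) classify_bins(value, spa_bins("temp"))

#' Build the full duration-climate table
#'
#' Runs [aggregate_duration()] for every phenology record, then appends SPA,
#' STA and the three classifications.
#'
#' @param weather daily weather table for all county-years.
#' @param phenology data.frame of phenology records (`county_id`, `year`,
#'   `crop`, `s1`..`s4`).
#' @param min_years,include_focal passed to the anomaly computations.
#' @return duration-climate data.frame with `spa`, `sta`, `pdsi_class`,
#'   `spa_class`, `sta_class` columns.
#' @export
climate_table <- function(weather, phenology, min_years = 5,
                          include_focal = TRUE) {
  wsp <- split(weather, paste(weather$county_id, weather$year))
  rows <- lapply(seq_len(nrow(phenology)), function(i) {
    rec <- phenology[i, ]
    aggregate_duration(wsp[[paste(rec$county_id, rec$year)]], rec)
  })
  panel <- do.call(rbind, rows)
  panel <- compute_spa(panel, min_years, include_focal)
  panel <- compute_sta(panel, min_years, include_focal)
  panel$pdsi_class <- classify_pdsi(panel$pdsi)
  panel$spa_class <- classify_spa(panel$spa)
  panel$sta_class <- classify_sta(panel$sta)
  panel
}
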