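# Phenological stage detection from two-band 8-day composites: vegetation
# index, spline smoothing to a daily grid, shape-model fitting for the
# interior stages, threshold crossings for emergence/maturity, county
# aggregation and validation against crop-progress reference dates.

#' Compute the wide dynamic range vegetation index
#'
#' WDRVI = (alpha * NIR - red) / (alpha * NIR + red), computed for good-quality
#' composites only. The small weighting coefficient linearizes the index at
#' high canopy cover relative to NDVI.
#'
#' @param series data.frame with `doy`, `ref_b1` (red), `ref_b2` (NIR) and
#'   `qc_flag` (`"good"`/`"bad"`; if absent all rows are taken as good).
#' @param alpha weighting coefficient, default 0.1.
#' @return data.frame (`doy`, `wdrvi`) for the good composites.
#' @export
compute_wdrvi <- function(series, alpha = 0.1) {
  if (alpha <= 0)
    stop_primecrop("alpha must be > 0", "primecrop_input_error")
  qc <- series$qc_flag %||% rep("good", nrow(series))
  keep <- qc == "good"
  if (!any(keep))
    stop_primecrop("all composites flagged bad", "primecrop_empty_error")
  b1 <- series$ref_b1[keep]; b2 <- series$ref_b2[keep]
  den <- alpha * b2 + b1
  if (any(den == 0))
    stop_primecrop("zero denominator in WDRVI (alpha*NIR + red = 0)",
                   "primecrop_undefined_error")
  data.frame(doy = series$doy[keep], wdrvi = (alpha * b2 - b1) / den)
}

#' Smooth composites to a daily vegetation-index series
#'
#' Fits a smoothing spline (smoothness chosen by generalized cross-validation)
#' through the good composites and evaluates it on a daily day-of-year grid,
#' interpolating gaps. Pixel-years with too few composites, too short a span
#' or a gap wider than 32 days are rejected with a quality error.
#'
#' @param wdrvi data.frame (`doy`, `wdrvi`) as from [compute_wdrvi()].
#' @param year calendar year carried through for bookkeeping.
#' @param min_composites,min_span_days,max_gap_days quality thresholds.
#' @return list of class `wdrvi_series`: `doy` (daily grid), `wdrvi`
#'   (clipped to [-1, 1]), `year`, `spar` (the selected smoothing parameter).
#' @export
smooth_daily <- function(wdrvi, year = NA_integer_, min_composites = 8,
                         min_span_days = 120, max_gap_days = 32) {
  ok <- is.finite(wdrvi$wdrvi)
  x <- wdrvi$doy[ok]; y <- wdrvi$wdrvi[ok]
  if (length(x) < min_composites)
    stop_primecrop(sprintf("only %d good composites (need >= %d)",
                           length(x), min_composites),
                   "primecrop_quality_error")
  if (diff(range(x)) < min_span_days)
    stop_primecrop("composite span too short", "primecrop_quality_error")
  if (max(diff(sort(x))) > max_gap_days)
    stop_primecrop("gap between composites exceeds limit",
                   "primecrop_quality_error")
  fit <- stats::smooth.spline(x, y, cv = FALSE)
  grid <- seq(min(x), max(x))
  vals <- clip(stats::predict(fit, grid)$y, -1, 1)
  structure(list(doy = grid, wdrvi = vals, year = year, spar = fit$spar),
            class = "wdrvi_series")
}

#' Build a reference shape model by averaging daily series
#'
#' Pointwise mean of daily smoothed vegetation-index series over calibration
#' years, with the crop's reference stage dates attached unchanged.
#'
#' @param daily_series list of `wdrvi_series` on a common daily grid.
#' @param reference_dates 4 strictly increasing DOYs.
#' @param crop crop name carried on the model.
#' @return list of class `shape_model`: `crop`, `doy`, `h`, `reference_dates`.
#' @export
build_shape_model <- function(daily_series, reference_dates,
                              crop = "maize") {
  if (length(daily_series) < 1)
    stop_primecrop("need at least one input series", "primecrop_input_error")
  grid <- daily_series[[1]]$doy
  for (s in daily_series) {
    if (length(s$doy) != length(grid) || any(s$doy != grid))
      stop_primecrop("input series are not on a common DOY grid",
                     "primecrop_input_error")
  }
  if (length(reference_dates) != 4 || any(diff(reference_dates) <= 0))
    stop_primecrop("reference_dates must be 4 strictly increasing DOYs",
                   "primecrop_input_error")
  if (min(reference_dates) < min(grid) || max(reference_dates) > max(grid))
    stop_primecrop("reference dates must lie inside the model grid",
                   "primecrop_input_error")
  h <- rowMeans(do.call(cbind, lapply(daily_series, `[[`, "wdrvi")))
  structure(list(crop = crop, doy = grid, h = h,
                 reference_dates = reference_dates),
            class = "shape_model")
}

#' Reference shape model from noise-free synthetic calibration years
#'
#' Emulates the calibration-site construction: simulates noise-free,
#' gap-free composites at the crop's reference stage dates, smooths them to
#' daily series and averages over the calibration years.
#'
#' @param config a [simulation_config()].
#' @param n_years number of (identical, noise-free) calibration years.
#' @return a `shape_model`.
#' @export
reference_shape_model <- function(config, n_years = 5) {
  cfg <- config
  cfg$composite_noise_sd <- 0
  cfg$missing_rate <- 0
  series <- lapply(seq_len(n_years), function(i) {
    rf <- simulate_reflectance(cfg$stage_date_means, cfg,
                               pixel = "REF", year = i)
    smooth_daily(compute_wdrvi(rf, cfg$alpha), year = i)
  })
  build_shape_model(series, cfg$stage_date_means, crop = cfg$crop)
}

#' Fit the shape model to an observed daily series
#'
#' Estimates the geometric transformation f(x) = yscale * h(xscale * x +
#' tshift) minimizing the RMSE between the transformed reference curve and the
#' observed daily series, via Levenberg-Marquardt. The reference curve is
#' evaluated by linear interpolation; arguments falling outside the model grid
#' are excluded from the loss.
#'
#' @param model a `shape_model`.
#' @param series a `wdrvi_series`.
#' @param init starting values `c(xscale, tshift, yscale)`.
#' @param lower,upper box bounds on the parameters.
#' @param min_overlap_days minimum number of in-grid days required.
#' @return list of class `smf_fit`: `xscale`, `tshift`, `yscale`, `rmse`,
#'   `converged`, `iterations`, `n_used`.
#' @export
fit_shape_model <- function(model, series, init = c(1, 0, 1),
                            lower = c(0.6, -60, 0.3),
                            upper = c(1.6, 60, 2.0),
                            min_overlap_days = 120) {
  x <- series$doy; y <- series$wdrvi
  h_at <- function(u) stats::approx(model$doy, model$h, xout = u,
                                    rule = 1)$y
  resid_fn <- function(p) {
    pred <- p[3] * h_at(p[1] * x + p[2])
    r <- pred - y
    r[!is.finite(r)] <- 0
    r
  }
  in_grid <- function(p) sum(is.finite(h_at(p[1] * x + p[2])))
  if (in_grid(init) < min_overlap_days)
    stop_primecrop("series/model overlap shorter than required at init",
                   "primecrop_input_error")
  fit <- minpack.lm::nls.lm(par = init, fn = resid_fn,
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  p <- fit$par
  used <- is.finite(h_at(p[1] * x + p[2]))
  r <- p[3] * h_at(p[1] * x + p[2])[used] - y[used]
  rmse <- sqrt(mean(r^2))
  converged <- fit$info %in% 1:4
  at_bound <- any(abs(p - lower) < 1e-8) || any(abs(p - upper) < 1e-8)
  if (at_bound)
    warning("shape-model fit parameter at a box bound",
            call. = FALSE)
  structure(list(xscale = p[1], tshift = p[2], yscale = p[3],
                 rmse = rmse, converged = converged,
                 iterations = fit$niter, n_used = sum(used),
                 at_bound = at_bound),
            class = "smf_fit")
}

#' Map reference stage dates through a fitted transformation
#'
#' A reference date d0 on the model's time axis corresponds to the observed
#' date x solving xscale * x + tshift = d0.
#'
#' @param fit an `smf_fit` (must have converged).
#' @param model the `shape_model` the fit used.
#' @param stages indices of reference dates to map (default interior stages
#'   2 and 3, the ones the shape-model fit identifies in the hybrid method).
#' @return named integer DOYs (rounded half-up).
#' @export
stage_dates_from_fit <- function(fit, model, stages = c(2, 3)) {
  if (!fit$converged)
    stop_primecrop("fit did not converge", "primecrop_input_error")
  d0 <- model$reference_dates[stages]
  x <- (d0 - fit$tshift) / fit$xscale
  out <- round_half_up(x)
  if (any(out < 1 | out > 366))
    stop_primecrop("mapped stage date outside [1, 366]",
                   "primecrop_range_error")
  stats::setNames(out, paste0("s", stages))
}

#' Detect emergence and maturity by threshold crossings
#'
#' Emergence is the last upward crossing of `up_threshold` before the peak;
#' maturity the first downward crossing of `down_threshold` after it.
#' Crossings are located by linear interpolation between daily points and
#' rounded to the nearest day.
#'
#' @param series a `wdrvi_series` (daily).
#' @param up_threshold,down_threshold crossing levels.
#' @param peak_doy DOY of the seasonal maximum (taken from the fitted shape
#'   model in the pipeline).
#' @return named numeric `c(emergence, maturity)` in days.
#' @export
detect_threshold_crossings <- function(series, up_threshold, down_threshold,
                                       peak_doy) {
  x <- series$doy; v <- series$wdrvi
  ip <- which.min(abs(x - peak_doy))
  up <- NA_real_
  if (ip >= 2) {
    for (i in seq_len(ip - 1)) {
      # upward crossing in (i, i+1]: below before, at/above after
      if (v[i] < up_threshold && v[i + 1] >= up_threshold) {
        frac <- (up_threshold - v[i]) / (v[i + 1] - v[i])
        up <- x[i] + frac * (x[i + 1] - x[i])
      }
    }
  }
  if (!is.finite(up))
    stop_primecrop("no upward threshold crossing before the peak",
                   "primecrop_detection_error")
  down <- NA_real_
  if (ip < length(x)) {
    for (i in ip:(length(x) - 1)) {
      if (v[i] >= down_threshold && v[i + 1] < down_threshold) {
        frac <- (v[i] - down_threshold) / (v[i] - v[i + 1])
        down <- x[i] + frac * (x[i + 1] - x[i])
        break
      }
    }
  }
  if (!is.finite(down))
    stop_primecrop("no downward threshold crossing after the peak",
                   "primecrop_detection_error")
  c(emergence = round_half_up(up), maturity = round_half_up(down))
}

#' Select pixels by crop fraction
#'
#' Keeps pixel-years whose crop fraction meets the cutoff (inclusive).
#'
#' @param cdl_fractions data.frame (`pixel_id`, `year`, `crop_fraction`).
#' @param min_fraction cutoff, default 0.8.
#' @return the input with a logical `keep` column.
#' @export
select_crop_pixels <- function(cdl_fractions, min_fraction = 0.8) {
  if (any(cdl_fractions$crop_fraction < 0 | cdl_fractions$crop_fraction > 1))
    stop_primecrop("crop fractions must be in [0, 1]",
                   "primecrop_input_error")
  cdl_fractions$keep <- cdl_fractions$crop_fraction >= min_fraction
  cdl_fractions
}

#' Aggregate pixel stage dates to county-year records
#'
#' County stage dates are the means over valid pixels, rounded to whole days;
#' durations are recomputed from the rounded dates.
#'
#' @param pixel_stages data.frame (`pixel_id`, `county_id`, `year`, `crop`,
#'   `s1`..`s4`).
#' @return data.frame of phenology records (`county_id`, `year`, `crop`,
#'   `s1`..`s4`, `d1`..`d3`, `n_pixels`).
#' @export
aggregate_to_county <- function(pixel_stages) {
  if (nrow(pixel_stages) == 0)
    stop_primecrop("no valid pixels to aggregate", "primecrop_input_error")
  sp <- split(pixel_stages,
              paste(pixel_stages$county_id, pixel_stages$year))
  out <- do.call(rbind, lapply(sp, function(g) {
    s <- round_half_up(colMeans(g[, c("s1", "s2", "s3", "s4")]))
    data.frame(county_id = g$county_id[1], year = g$year[1],
               crop = g$crop[1],
               s1 = s[1], s2 = s[2], s3 = s[3], s4 = s[4],
               d1 = s[2] - s[1], d2 = s[3] - s[2], d3 = s[4] - s[3],
               n_pixels = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  bad <- out$d1 <= 0 | out$d2 <= 0 | out$d3 <= 0
  attr(out, "excluded_nonincreasing") <- sum(bad)
  out[!bad, ]
}

#' Reference stage date from weekly crop-progress area ratios
#'
#' Fits a two-parameter logistic ratio(t) = 100 / (1 + exp(-k (t - t50))) to
#' the weekly area ratios by least squares and returns the 50%-crossing date.
#'
#' @param week_doy,area_ratio weekly DOYs and area ratios in [0, 100].
#' @return list: `t50` (fitted, continuous), `doy` (rounded to day), `k`.
#' @export
interpolate_cpr <- function(week_doy, area_ratio) {
  if (any(area_ratio < 0 | area_ratio > 100))
    stop_primecrop("area ratios must be in [0, 100]", "primecrop_input_error")
  if (!any(area_ratio < 50) || !any(area_ratio > 50)) {
    if (any(area_ratio == 50)) {
      # flat-at-50 degenerate case is still undefined for the fit
    }
    if (!any(area_ratio > 50) || !any(area_ratio < 50))
      stop_primecrop("area ratios never straddle 50%",
                     "primecrop_interpolation_error")
  }
  o <- order(week_doy)
  t <- week_doy[o]; y <- area_ratio[o]
  t50_init <- stats::approx(y + seq_along(y) * 1e-9, t, xout = 50)$y
  fit <- minpack.lm::nls.lm(
    par = c(k = 0.2, t50 = t50_init),
    fn = function(p) 100 / (1 + exp(-p[1] * (t - p[2]))) - y,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  list(t50 = fit$par[["t50"]], doy = round_half_up(fit$par[["t50"]]),
       k = fit$par[["k"]])
}

#' Root mean square error between estimated and reference dates
#'
#' @param estimated,reference paired numeric vectors (days).
#' @param grouping optional factor; RMSE is returned per group.
#' @return a number, or a named numeric per group.
#' @export
evaluate_rmse <- function(estimated, reference, grouping = NULL) {
  if (length(estimated) != length(reference) || length(estimated) < 1)
    stop_primecrop("estimated/reference must be paired and non-empty",
                   "primecrop_input_error")
  if (is.null(grouping)) return(sqrt(mean((estimated - reference)^2)))
  vapply(split(seq_along(estimated), grouping), function(i) {
    sqrt(mean((estimated[i] - reference[i])^2))
  }, numeric(1))
}

#' Detect phenology for every pixel-year and aggregate to counties
#'
#' The full hybrid detection: crop-fraction filtering, index computation,
#' spline smoothing, shape-model fitting (interior stages), threshold
#' crossings (emergence/maturity), per-record stage-order checks, and county
#' aggregation. Pixel-years failing any step are excluded and counted in the
#' run report rather than imputed.
#'
#' @param reflectance composite table (`pixel_id`, `county_id`, `year`,
#'   `doy`, `ref_b1`, `ref_b2`, `qc_flag`).
#' @param cdl crop fraction table (`pixel_id`, `year`, `crop_fraction`).
#' @param model a `shape_model`.
#' @param config a [simulation_config()] (supplies thresholds and crop).
#' @param min_fraction crop-fraction cutoff.
#' @param rmse_max converged fits with RMSE above this are excluded as poor.
#' @return list: `pixels` (per pixel-year stage dates), `county` (phenology
#'   records), `report` (named exclusion counts).
#' @export
detect_phenology <- function(reflectance, cdl, model, config,
                             min_fraction = 0.8, rmse_max = 0.1) {
  cdl <- select_crop_pixels(cdl, min_fraction)
  keep_key <- paste(cdl$pixel_id, cdl$year)[cdl$keep]
  report <- c(low_fraction = 0, quality = 0, fit = 0, detection = 0,
              stage_order = 0, ok = 0)
  sp <- split(reflectance, paste(reflectance$pixel_id, reflectance$year))
  rows <- vector("list", length(sp))
  peak_ref <- model$doy[which.max(model$h)]
  for (nm in names(sp)) {
    g <- sp[[nm]]
    if (!nm %in% keep_key) {
      report["low_fraction"] <- report["low_fraction"] + 1
      next
    }
    res <- tryCatch({
      w <- compute_wdrvi(g, config$alpha)
      daily <- smooth_daily(w, year = g$year[1])
      fit <- suppressWarnings(fit_shape_model(model, daily))
      if (!fit$converged || fit$rmse > rmse_max)
        stop_primecrop("poor shape-model fit", "primecrop_fit_error")
      s23 <- stage_dates_from_fit(fit, model)
      peak_doy <- (peak_ref - fit$tshift) / fit$xscale
      em <- detect_threshold_crossings(daily, config$up_threshold,
                                       config$down_threshold, peak_doy)
      s <- c(em[["emergence"]], s23[["s2"]], s23[["s3"]], em[["maturity"]])
      if (any(diff(s) <= 0))
        stop_primecrop("detected stages out of order",
                       "primecrop_order_error")
      data.frame(pixel_id = g$pixel_id[1], county_id = g$county_id[1],
                 year = g$year[1], crop = config$crop,
                 s1 = s[1], s2 = s[2], s3 = s[3], s4 = s[4],
                 stringsAsFactors = FALSE)
    }, primecrop_error = function(e) e)
    if (inherits(res, "primecrop_error")) {
      cls <- class(res)[1]
      slot <- switch(cls,
                     primecrop_quality_error = "quality",
                     primecrop_empty_error = "quality",
                     primecrop_fit_error = "fit",
                     primecrop_input_error = "fit",
                     primecrop_detection_error = "detection",
                     primecrop_range_error = "detection",
                     primecrop_order_error = "stage_order",
                     "fit")
      report[slot] <- report[slot] + 1
    } else {
      report["ok"] <- report["ok"] + 1
      rows[[nm]] <- res
    }
  }
  pixels <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  county <- if (is.null(pixels) || nrow(pixels) == 0) NULL else
    aggregate_to_county(pixels)
  list(pixels = pixels, county = county, report = report)
}
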