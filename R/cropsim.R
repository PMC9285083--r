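# Minimal daily soil-water-balance crop simulator with an explicit
# root-deepening priming mechanism. The plant draws first on a finite deep
# moisture reserve at a rate proportional to root depth beyond a base depth,
# then on a shallow store recharged by rain; water stress accelerates root
# deepening while roots are still growing. That is the embodied priming
# hypothesis: an early drought deepens roots, opening access to more deep
# moisture during a later drought.

#' Crop simulator parameters
#'
#' @param crop `"maize"` or `"soybean"` (sets defaults).
#' @param sowing_doy sowing day of year.
#' @param season_length days from sowing to harvest.
#' @param max_lai peak leaf area index.
#' @param potential_yield stress-free yield, Mg/Ha.
#' @param base_root_depth root depth at sowing, m; the shallow store capacity
#'   is `soil_whc * base_root_depth`.
#' @param max_root_depth maximum root depth, m.
#' @param root_growth_rate unstressed deepening rate, m/day; roots grow
#'   during the first two thirds of the season.
#' @param stress_root_boost multiplier (>= 1) on root growth under full
#'   stress; 1 disables the priming mechanism.
#' @param soil_whc water holding capacity, mm per m of soil; the deep
#'   reserve capacity is `soil_whc * (max_root_depth - base_root_depth)`.
#' @param kc crop evapotranspiration coefficient.
#' @param deep_supply_max deep-moisture supply (mm/day) at full root depth.
#' @param extract_frac fraction of the shallow store extractable per day.
#' @param init_shallow_frac initial shallow-store fill fraction.
#' @param init_deep_frac initial deep-reserve fill fraction.
#' @param ra_mm extraterrestrial-radiation equivalent (mm/day) in the
#'   temperature-based reference ET formula.
#' @param stress_sensitivity length-3 daily yield sensitivities to stress in
#'   the vegetative, early-reproductive and late-reproductive thirds of the
#'   season (late > early).
#' @return list of class `crop_params`.
#' @export
crop_params <- function(crop = c("maize", "soybean"),
                        sowing_doy = 125, season_length = 150,
                        max_lai = NULL, potential_yield = NULL,
                        base_root_depth = 0.4, max_root_depth = 2.0,
                        root_growth_rate = 0.008,
                        stress_root_boost = 3,
                        soil_whc = 180, kc = 1.25,
                        deep_supply_max = 3.5,
                        extract_frac = 1.0,
                        init_shallow_frac = 0.8,
                        init_deep_frac = 1.0,
                        ra_mm = 15,
                        stress_sensitivity = c(0, 0.02, 0.028)) {
  crop <- match.arg(crop)
  max_lai <- max_lai %||% if (crop == "maize") 6 else 5
  potential_yield <- potential_yield %||% if (crop == "maize") 11 else 3.8
  p <- list(crop = crop, sowing_doy = sowing_doy,
            season_length = season_length, max_lai = max_lai,
            potential_yield = potential_yield,
            base_root_depth = base_root_depth,
            max_root_depth = max_root_depth,
            root_growth_rate = root_growth_rate,
            stress_root_boost = stress_root_boost,
            soil_whc = soil_whc, kc = kc,
            deep_supply_max = deep_supply_max,
            extract_frac = extract_frac,
            init_shallow_frac = init_shallow_frac,
            init_deep_frac = init_deep_frac,
            ra_mm = ra_mm, stress_sensitivity = stress_sensitivity)
  if (p$base_root_depth > p$max_root_depth)
    stop_primecrop("base_root_depth must be <= max_root_depth",
                   "primecrop_config_error")
  if (p$stress_root_boost < 1)
    stop_primecrop("stress_root_boost must be >= 1",
                   "primecrop_config_error")
  pos <- c("season_length", "max_lai", "potential_yield", "base_root_depth",
           "soil_whc", "kc", "ra_mm")
  for (nm in pos) if (p[[nm]] <= 0)
    stop_primecrop(paste(nm, "must be positive"), "primecrop_config_error")
  if (diff(stress_sensitivity[c(1, 3)]) <= 0)
    stop_primecrop("late-window stress sensitivity must exceed early-window",
                   "primecrop_config_error")
  structure(p, class = "crop_params")
}

# Hargreaves-type temperature-based reference ET (mm/day).
reference_et <- function(tmax, tmin, ra_mm) {
  tmean <- (tmax + tmin) / 2
  pmax(0, 0.0023 * ra_mm * (tmean + 17.8) * sqrt(pmax(tmax - tmin, 0)))
}

#' Run the crop simulator over one season
#'
#' Daily update: crop water demand is the temperature-based reference ET
#' scaled by the crop coefficient and the potential canopy cover; supply is
#' the root-depth-proportional draw on the finite deep reserve plus the
#' extractable shallow water; stress = 1 - supplied/demand. Stress
#' accelerates root deepening (while roots grow, i.e. the first two thirds
#' of the season) and multiplies the yield down through the window-specific
#' sensitivities. The reported LAI is the potential canopy scaled down by
#' accumulated stress; demand uses the potential canopy so that scenario
#' comparisons differ only through the water balance.
#'
#' @param weather daily table with `doy`, `tmax_c`, `tmin_c`, `precip_mm`
#'   covering the whole season.
#' @param params a [crop_params()].
#' @return list of class `crop_run`: `daily` (shallow soil water, deep
#'   reserve, root depth, LAI, stress, fluxes), `yield`, `final_root_depth`,
#'   `stress_index` (mean daily stress).
#' @export
run_crop <- function(weather, params) {
  days <- params$sowing_doy:(params$sowing_doy + params$season_length - 1)
  idx <- match(days, weather$doy)
  if (anyNA(idx))
    stop_primecrop("weather does not cover the full season",
                   "primecrop_input_error")
  w <- weather[idx, ]
  n <- params$season_length
  cap <- params$soil_whc * params$base_root_depth
  sw <- params$init_shallow_frac * cap
  deep <- params$init_deep_frac * params$soil_whc *
    (params$max_root_depth - params$base_root_depth)
  rd <- params$base_root_depth
  root_days <- floor(2 * n / 3)
  third <- ceiling(n / 3)
  sens <- params$stress_sensitivity[pmin(3, (seq_len(n) - 1) %/% third + 1)]

  frac <- seq_len(n) / n
  lai_pot <- params$max_lai * sin(pi * pmin(1, pmax(0, frac))) ^ 1.5

  out <- data.frame(doy = days, precip = w$precip_mm,
                    et0 = reference_et(w$tmax_c, w$tmin_c, params$ra_mm))
  out$demand <- out$aet_shallow <- out$aet_deep <- out$drainage <-
    out$soil_water <- out$deep_reserve <- out$root_depth <- out$lai <-
    out$stress <- NA_real_

  root_span <- params$max_root_depth - params$base_root_depth
  yield_mult <- 1
  cum_stress <- 0
  for (i in seq_len(n)) {
    demand <- params$kc * out$et0[i] * min(1, lai_pot[i] / 3)
    deep_rate <- params$deep_supply_max *
      (rd - params$base_root_depth) / root_span
    aet_deep <- min(demand, deep_rate, deep)
    deep <- deep - aet_deep
    aet_shallow <- min(demand - aet_deep, params$extract_frac * sw)
    supplied <- aet_deep + aet_shallow
    stress <- if (demand > 0) max(0, 1 - supplied / demand) else 0
    if (stress < 1e-12) stress <- 0
    cum_stress <- cum_stress + stress

    if (i <= root_days) {
      growth <- params$root_growth_rate *
        (1 + (params$stress_root_boost - 1) * stress)
      rd <- min(params$max_root_depth, rd + growth)
    }

    raw <- sw + w$precip_mm[i] - aet_shallow
    drainage <- max(0, raw - cap)
    sw <- raw - drainage

    yield_mult <- yield_mult * (1 - sens[i] * stress)

    out$demand[i] <- demand; out$aet_shallow[i] <- aet_shallow
    out$aet_deep[i] <- aet_deep; out$drainage[i] <- drainage
    out$soil_water[i] <- sw; out$deep_reserve[i] <- deep
    out$root_depth[i] <- rd
    out$lai[i] <- lai_pot[i] * (1 - 0.4 * cum_stress / i)
    out$stress[i] <- stress
  }
  structure(list(daily = out,
                 yield = params$potential_yield * max(0, yield_mult),
                 final_root_depth = rd,
                 stress_index = mean(out$stress)),
            class = "crop_run")
}

#' Compare simulated yields across priming scenarios
#'
#' Runs the simulator over one or more weather realizations per scenario and
#' reports mean yield and mean final root depth per scenario, plus flags for
#' the qualitative ordering the priming hypothesis predicts:
#' yield(control) >= yield(priming) >= yield(nonpriming) and
#' root depth(priming) > root depth(control).
#'
#' @param params a [crop_params()].
#' @param scenarios named list (`control`, `nonpriming`, `priming`), each a
#'   list of daily weather tables.
#' @return list of class `priming_experiment`: `summary` (per-scenario mean
#'   yield/root depth/n), `yield_ordering_holds`, `root_depth_ordering_holds`.
#' @export
priming_experiment <- function(params, scenarios) {
  if (length(scenarios) == 0 || any(!vapply(scenarios, length, 0L) >= 1))
    stop_primecrop("every scenario needs >= 1 weather realization",
                   "primecrop_input_error")
  summ <- do.call(rbind, lapply(names(scenarios), function(nm) {
    runs <- lapply(scenarios[[nm]], run_crop, params = params)
    data.frame(scenario = nm,
               mean_yield = mean(vapply(runs, `[[`, 0, "yield")),
               mean_root_depth = mean(vapply(runs, `[[`, 0,
                                             "final_root_depth")),
               n = length(runs), stringsAsFactors = FALSE)
  }))
  y <- stats::setNames(summ$mean_yield, summ$scenario)
  r <- stats::setNames(summ$mean_root_depth, summ$scenario)
  ord <- all(c("control", "priming", "nonpriming") %in% names(y)) &&
    y[["control"]] >= y[["priming"]] && y[["priming"]] >= y[["nonpriming"]]
  rord <- all(c("control", "priming") %in% names(r)) &&
    r[["priming"]] > r[["control"]]
  structure(list(summary = summ, yield_ordering_holds = ord,
                 root_depth_ordering_holds = rord),
            class = "priming_experiment")
}

#' Scenario weather for the crop simulator
#'
#' Builds control / nonpriming / priming weather realizations from the
#' synthetic weather generator: the nonpriming scenario scales precipitation
#' down in a late-season window, the priming scenario in both an early and
#' the same late window, and the control in neither. Realizations are paired:
#' draw k shares its weather across scenarios except inside the scaled
#' windows. Every scenario additionally receives the same profile-recharging
#' storm just after the early window, so the soil stores of all scenarios
#' re-equalize before the reproductive window and the only persistent legacy
#' of the early drought is root depth — the mechanism under study.
#'
#' @param config a [simulation_config()].
#' @param params a [crop_params()] (supplies the season geometry).
#' @param n_draws realizations per scenario.
#' @param drought_factor precipitation multiplier inside stress windows.
#' @param storm_mm recharge storm depth (mm).
#' @return named list of lists of daily weather tables.
#' @export
cropsim_scenarios <- function(config, params, n_draws = 10,
                              drought_factor = 0.05, storm_mm = 80) {
  s0 <- params$sowing_doy
  early <- c(s0 + 10, s0 + 44)
  late <- c(s0 + 100, s0 + 140)
  win <- function(w) data.frame(start_doy = w[1], end_doy = w[2],
                                factor = drought_factor)
  counties <- county_ids(config)
  years <- rep(config$years, length.out = n_draws)
  ctys <- rep(counties, each = ceiling(n_draws / length(counties)))[
    seq_len(n_draws)]
  build <- function(windows) {
    lapply(seq_len(n_draws), function(k) {
      w <- simulate_weather(config, ctys[k], years[k],
                            precip_windows = windows)
      w$precip_mm[w$doy == early[2] + 2] <-
        w$precip_mm[w$doy == early[2] + 2] + storm_mm
      w
    })
  }
  list(control = build(NULL),
       nonpriming = build(win(late)),
       priming = build(rbind(win(early), win(late))))
}
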