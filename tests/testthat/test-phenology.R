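test_that("vegetation index arithmetic matches its definition", {
  s <- data.frame(doy = c(100, 108, 116),
                  ref_b1 = c(0.05, 0.045, 0),
                  ref_b2 = c(0.45, 0.45, 0.4),
                  qc_flag = "good")
  w <- compute_wdrvi(s, alpha = 0.1)
  expect_equal(w$wdrvi[1], -0.005 / 0.095)          # hand arithmetic
  expect_equal(w$wdrvi[2], 0)                        # red = alpha * NIR
  expect_equal(w$wdrvi[3], 1)                        # red = 0
  expect_true(all(w$wdrvi >= -1 & w$wdrvi <= 1))
  s$qc_flag <- "bad"
  expect_error(compute_wdrvi(s), class = "primecrop_empty_error")
  expect_error(compute_wdrvi(data.frame(doy = 1, ref_b1 = 0, ref_b2 = 0,
                                        qc_flag = "good")),
               class = "primecrop_undefined_error")
})

test_that("daily smoothing reproduces a noise-free curve and fills gaps", {
  cfg <- noiseless_config()
  stages <- c(150, 200, 240, 265)
  rf <- simulate_reflectance(stages, cfg, "PX", 2001)
  w <- compute_wdrvi(rf, cfg$alpha)
  sm <- smooth_daily(w, 2001)
  at <- match(w$doy, sm$doy)
  expect_lt(max(abs(sm$wdrvi[at] - w$wdrvi)), 1e-3)
  # leave one interior composite out: the filled value stays close
  drop_i <- which(w$doy == 201)
  sm2 <- smooth_daily(w[-drop_i, ], 2001)
  truth <- canopy_curve(201, stages, cfg)
  expect_lt(abs(sm2$wdrvi[sm2$doy == 201] - truth), 0.05)
  # too few composites is a quality error
  expect_error(smooth_daily(w[1:5, ], 2001),
               class = "primecrop_quality_error")
  # too-short span is a quality error
  short <- w[w$doy >= 150 & w$doy <= 250, ]
  expect_error(smooth_daily(short, 2001), class = "primecrop_quality_error")
  # a wide interior gap is a quality error
  gap <- w[w$doy < 150 | w$doy > 190, ]
  expect_error(smooth_daily(gap, 2001), class = "primecrop_quality_error")
})

test_that("shape model construction averages pointwise", {
  doy <- 100:300
  h <- sin((doy - 100) / 60)
  a <- as_wdrvi_series(doy, h)
  b <- as_wdrvi_series(doy, h + 0.2)
  ref <- c(150, 200, 240, 265)
  m1 <- build_shape_model(list(a), ref)
  expect_equal(m1$h, h)
  m2 <- build_shape_model(list(a, a), ref)
  expect_equal(m2$h, h)
  m3 <- build_shape_model(list(a, b), ref)
  expect_equal(m3$h, h + 0.1)
  expect_error(build_shape_model(list(a, as_wdrvi_series(101:301, h)), ref),
               class = "primecrop_input_error")
})

test_that("shape-model fitting recovers identity, shift and amplitude transforms", {
  cfg <- noiseless_config()
  m <- reference_shape_model(cfg)
  ident <- fit_shape_model(m, as_wdrvi_series(m$doy, m$h))
  expect_true(ident$converged)
  expect_equal(c(ident$xscale, ident$tshift, ident$yscale), c(1, 0, 1),
               tolerance = 1e-6)
  expect_lt(ident$rmse, 1e-9)

  # series(x) = h(x - 10): expect xscale 1, tshift -10
  rf <- simulate_reflectance(cfg$stage_date_means + 10, cfg, "PX", 2001)
  sh <- smooth_daily(compute_wdrvi(rf, cfg$alpha), 2001)
  f <- fit_shape_model(m, sh)
  expect_equal(f$xscale, 1, tolerance = 0.01)
  expect_equal(f$tshift, -10, tolerance = 0.5)

  sc <- fit_shape_model(m, as_wdrvi_series(m$doy, 0.9 * m$h))
  expect_equal(sc$yscale, 0.9, tolerance = 0.01)
  expect_lt(sc$rmse, 1e-6)
})

test_that("reference dates map through the fitted transformation", {
  cfg <- noiseless_config()
  m <- reference_shape_model(cfg)
  fit <- function(xs, ts) structure(list(xscale = xs, tshift = ts,
                                         yscale = 1, converged = TRUE),
                                    class = "smf_fit")
  expect_equal(unname(stage_dates_from_fit(fit(1, 0), m, 2)), 200)
  expect_equal(unname(stage_dates_from_fit(fit(1, -10), m, 2)), 210)
  m250 <- m; m250$reference_dates[3] <- 250
  expect_equal(unname(stage_dates_from_fit(fit(1.25, 0), m250, 3)), 200)
  expect_error(stage_dates_from_fit(fit(0.7, -200), m, 2),
               class = "primecrop_range_error")
})

test_that("threshold crossings are located by linear interpolation", {
  doy <- 100:300
  v <- pmin(0, -0.9 + 0.02 * (doy - 130))          # rises through -0.68 at 141
  v[doy > 250] <- -0.9                              # falls after the peak
  s <- as_wdrvi_series(doy, v)
  cr <- detect_threshold_crossings(s, -0.68, -0.68, peak_doy = 200)
  expect_equal(unname(cr["emergence"]), 141)
  # a daily point exactly on the threshold, rising
  v2 <- c(seq(-0.8, -0.68, length.out = 51),   # hits -0.68 exactly at 150
          seq(-0.67, 0, length.out = 100),
          seq(-0.02, -0.95, length.out = 50))
  s2 <- as_wdrvi_series(100:300, v2)
  cr2 <- detect_threshold_crossings(s2, -0.68, -0.9, peak_doy = 250)
  expect_equal(unname(cr2["emergence"]), 150)
  # series everywhere above the threshold: detection failure
  s3 <- as_wdrvi_series(doy, rep(0, length(doy)))
  expect_error(detect_threshold_crossings(s3, -0.68, -0.68, 200),
               class = "primecrop_detection_error")
})

test_that("crop-fraction filtering keeps the cutoff inclusive", {
  cdl <- data.frame(pixel_id = c("a", "b", "c"), year = 2000,
                    crop_fraction = c(0.85, 0.50, 0.80))
  out <- select_crop_pixels(cdl)
  expect_equal(out$keep, c(TRUE, FALSE, TRUE))
  expect_error(select_crop_pixels(data.frame(pixel_id = "a", year = 2000,
                                             crop_fraction = 1.2)),
               class = "primecrop_input_error")
})

test_that("county aggregation averages pixel dates then recomputes durations", {
  px <- data.frame(pixel_id = c("a", "b"), county_id = "C1", year = 2000,
                   crop = "maize", s1 = c(148, 150), s2 = c(200, 202),
                   s3 = c(240, 240), s4 = c(264, 266))
  rec <- aggregate_to_county(px)
  expect_equal(rec$s2, 201)
  expect_equal(rec$d1, 201 - 149)
  expect_equal(rec$n_pixels, 2)
  one <- aggregate_to_county(px[1, ])
  expect_equal(unlist(one[, c("s1", "s2", "s3", "s4")], use.names = FALSE),
               c(148, 200, 240, 264))
  expect_error(aggregate_to_county(px[0, ]), class = "primecrop_input_error")
})

test_that("crop-progress interpolation finds the 50% crossing date", {
  sym <- interpolate_cpr(c(180, 187, 194, 201), c(0, 25, 75, 100))
  expect_lt(abs(sym$t50 - 190.5), 0.5)
  mid <- interpolate_cpr(c(183, 190, 197), c(10, 50, 90))
  expect_equal(mid$doy, 190)
  expect_error(interpolate_cpr(c(180, 187), c(10, 40)),
               class = "primecrop_interpolation_error")
})

test_that("date RMSE follows its closed form", {
  expect_equal(evaluate_rmse(c(150, 200), c(150, 200)), 0)
  expect_equal(evaluate_rmse(c(153, 203, 243), c(150, 200, 240)), 3)
  expect_equal(evaluate_rmse(c(3, -3), c(0, 0)), 3)
  g <- evaluate_rmse(c(3, -3, 1), c(0, 0, 0), grouping = c("a", "a", "b"))
  expect_equal(unname(g), c(3, 1))
  expect_error(evaluate_rmse(numeric(0), numeric(0)),
               class = "primecrop_input_error")
})

test_that("shifting a series shifts detected dates equivariantly", {
  cfg <- noiseless_config()
  m <- reference_shape_model(cfg)
  base_rf <- simulate_reflectance(cfg$stage_date_means, cfg, "PX", 2001)
  base <- smooth_daily(compute_wdrvi(base_rf, cfg$alpha), 2001)
  f0 <- fit_shape_model(m, base)
  d0 <- stage_dates_from_fit(f0, m)
  for (k in c(5, -7)) {
    rf <- simulate_reflectance(cfg$stage_date_means + k, cfg, "PX", 2001)
    s <- smooth_daily(compute_wdrvi(rf, cfg$alpha), 2001)
    f <- fit_shape_model(m, s)
    d <- stage_dates_from_fit(f, m)
    expect_lt(max(abs(d - (d0 + k))), 0.51)
    # spline re-discretization moves the residual floor slightly; both fits
    # stay essentially exact
    expect_lt(max(f$rmse, f0$rmse), 5e-3)
    # tshift moves by -k * xscale
    expect_equal(f$tshift, f0$tshift - k * f$xscale, tolerance = 0.5)
  }
})

test_that("full detection emits ordered stages and a complete exclusion report", {
  cfg <- small_config(seed = 31)
  sc <- make_scenario(cfg)
  m <- reference_shape_model(cfg)
  ph <- detect_phenology(sc$reflectance, sc$cdl, m, cfg)
  expect_true(all(ph$pixels$s1 < ph$pixels$s2 &
                    ph$pixels$s2 < ph$pixels$s3 &
                    ph$pixels$s3 < ph$pixels$s4))
  expect_true(all(ph$county$d1 > 0 & ph$county$d2 > 0 & ph$county$d3 > 0))
  n_py <- length(unique(paste(sc$reflectance$pixel_id,
                              sc$reflectance$year)))
  expect_equal(sum(ph$report), n_py)
  expect_gt(ph$report[["low_fraction"]], 0)
})
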