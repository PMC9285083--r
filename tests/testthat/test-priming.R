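make_dc <- function(v1, v2, v3, col = "pdsi") {
  out <- data.frame(county_id = "C1", year = 2000,
                    duration = c("D1", "D2", "D3"))
  out[[col]] <- c(v1, v2, v3)
  out
}

test_that("group windows apply as printed, strict at the bounds", {
  rules <- default_group_rules("pdsi")
  lab <- function(...) assign_groups(make_dc(...), rules)$label
  expect_equal(lab(-2.5, 0.0, -2.8), "priming")
  expect_equal(lab(0.5, 0.0, -2.8), "nonpriming")
  expect_equal(lab(0, 0, 0), "control")
  expect_equal(lab(-2.5, -2.5, -2.5), "excluded")   # D2 outside its window
  expect_equal(lab(-2, 0, -2.8), "excluded")        # exactly on a bound
  # text variant narrows the nonpriming D1 window to (0, 2)
  txt <- default_group_rules("pdsi", pdsi_d1_variant = "text")
  expect_equal(assign_groups(make_dc(-0.5, 0, -2.8), txt)$label, "excluded")
  expect_equal(assign_groups(make_dc(0.5, 0, -2.8), txt)$label, "nonpriming")
  # missing duration rows are excluded
  dc <- make_dc(-2.5, 0, -2.8)[1:2, ]
  expect_equal(assign_groups(dc, rules)$label, "excluded")
})

test_that("group assignment agrees with a truth-table oracle over all bin combinations", {
  reps <- list(pdsi = c(-3, -1, 0, 1, 3),
               spa = c(-3, -1, 0, 1, 3),
               sta = c(-3, -1, 0, 1, 3))
  for (idx in c("pdsi", "spa", "sta")) {
    rules <- default_group_rules(idx)
    combos <- expand.grid(v1 = reps[[idx]], v2 = reps[[idx]],
                          v3 = reps[[idx]])
    got <- vapply(seq_len(nrow(combos)), function(i) {
      assign_groups(make_dc(combos$v1[i], combos$v2[i], combos$v3[i],
                            col = idx), rules)$label
    }, character(1))
    want <- vapply(seq_len(nrow(combos)), function(i) {
      oracle_group(combos$v1[i], combos$v2[i], combos$v3[i], rules)
    }, character(1))
    expect_equal(got, want, info = idx)
  }
})

test_that("mitigation arithmetic reproduces the printed worked example", {
  m <- mitigation_metrics(0.44, 0.26, -0.11, mean_yield = 9.77)
  expect_equal(m$mitigation_abs, 0.37)
  expect_equal(round(m$mitigation_frac, 3), 0.673)
  expect_equal(round(m$pct_of_mean_yield, 1), 3.8)
  z <- mitigation_metrics(0.4, 0.1, 0.1)
  expect_equal(z$mitigation_abs, 0)
  expect_equal(z$mitigation_frac, 0)
  full <- mitigation_metrics(0.4, 0.4, -0.1)
  expect_equal(full$mitigation_frac, 1)
  und <- mitigation_metrics(0.1, 0.2, 0.3)
  expect_true(is.na(und$mitigation_frac))
  expect_match(und$note, "undefined")
})

test_that("group comparison is calibrated under the null and powered under separation", {
  # null: identical groups give uniform p-values
  ps <- vapply(1:500, function(s) {
    set.seed(s)
    x <- stats::rnorm(60)
    compare_groups(c(x, stats::rnorm(10)),
                   c(rep(c("priming", "nonpriming"), each = 30),
                     rep("control", 10)))$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # power: 3 pooled SDs apart at n = 30 per group rejects essentially always
  rejects <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    r <- compare_groups(
      c(stats::rnorm(30, 3), stats::rnorm(30, 0), stats::rnorm(10, 1.5)),
      rep(c("priming", "nonpriming", "control"), c(30, 30, 10)))
    r$p_value < 0.05
  }, logical(1))
  expect_gte(sum(rejects), 99)
  expect_error(compare_groups(1:5, c("priming", "priming", "nonpriming",
                                     "control", "control")),
               "nonpriming", class = "primecrop_insufficient_data")
})

test_that("priming frequency counts conserve totals", {
  lab <- data.frame(county_id = c("A", "A", "A", "B", "B"),
                    label = c("priming", "control", "priming",
                              "nonpriming", "excluded"))
  fr <- county_priming_frequency(lab)
  expect_equal(fr$n_priming[fr$county_id == "A"], 2)
  expect_equal(fr$n_priming[fr$county_id == "B"], 0)
  expect_equal(sum(fr$n_priming), sum(lab$label == "priming"))
})

test_that("LAI group statistics flag only genuinely shifted cells", {
  set.seed(9)
  n <- 50
  labels <- data.frame(
    county_id = sprintf("C%03d", 1:(3 * n)),
    year = 2000,
    label = rep(c("control", "nonpriming", "priming"), each = n))
  lai <- do.call(rbind, lapply(c("D1", "D2", "D3"), function(d) {
    x <- stats::rnorm(3 * n, 3, 0.3)
    data.frame(county_id = labels$county_id, year = 2000, duration = d,
               lai = x + ifelse(d == "D2" & labels$label == "priming",
                                0.5, 0))
  }))
  out <- lai_group_stats(lai, labels)
  pw <- out$pairwise
  d2_pr <- pw$duration == "D2" & pw$group_b == "priming"
  expect_true(all(pw$significant[d2_pr]))
  expect_false(any(pw$significant[pw$duration == "D1"]))
  expect_false(any(pw$significant[pw$duration == "D3" &
                                    pw$group_b == "priming" &
                                    pw$group_a == "control"]))
  # identical LAI everywhere: equal means, zero SD
  flat <- lai; flat$lai <- 2
  out2 <- lai_group_stats(flat, labels)
  expect_true(all(out2$stats$mean == 2))
  expect_true(all(out2$stats$sd == 0))
  expect_error(lai_group_stats(transform(lai, lai = -lai), labels),
               class = "primecrop_input_error")
})

test_that("estimated mitigation converges to the injected fraction", {
  # generator truth: loss 1.0 Mg/Ha, mitigation 0.5, labels taken from truth
  cfg <- simulation_config(seed = 77, n_counties = 40, years = 2000:2018,
                           pixels_per_county = 1, drought_loss = 1,
                           priming_mitigation_frac = 0.5,
                           yield_noise_sd = 0.3)
  sc <- make_scenario(cfg)
  lab <- sc$truth$labels
  panel <- make_panel(sc$yields, sc$duration_climate_true)
  an <- compute_anomaly(panel, fit_trend_c2(panel))
  res <- compare_groups(
    an$anomaly_mg_ha,
    lab$label[match(paste(an$county_id, an$year),
                    paste(lab$county_id, lab$year))])
  expect_lt(abs(res$mitigation_abs - 0.5), 0.1)
  expect_lt(abs(res$mitigation_frac - 0.5), 0.1)
  expect_lt(res$p_value, 0.05)
})
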