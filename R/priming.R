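# Group delineation (priming / nonpriming / control) from duration exposure,
# group comparison statistics and mitigation arithmetic.

#' Default group delineation windows
#'
#' Numeric windows per duration for the priming, nonpriming and control
#' groups, for one of the three exposure indices. All bounds are strict
#' (values exactly on a bound fall outside the window). Priming and
#' nonpriming differ only in the early (D1) window: priming requires early
#' exposure there, nonpriming requires near-normal conditions; both require a
#' late (D3) exposure, and the control group is near normal in all three.
#'
#' @param index `"pdsi"`, `"spa"` or `"sta"`.
#' @param pdsi_d1_variant for the drought-index rules, the nonpriming D1
#'   window: `"table"` (-2, 2) or `"text"` (0, 2).
#' @return list of class `group_rules`: `index` plus one list per group of
#'   `d1`/`d2`/`d3` windows `c(lo, hi)`.
#' @export
default_group_rules <- function(index = c("pdsi", "spa", "sta"),
                                pdsi_d1_variant = c("table", "text")) {
  index <- match.arg(index)
  pdsi_d1_variant <- match.arg(pdsi_d1_variant)
  rules <- switch(index,
    pdsi = list(
      priming = list(d1 = c(-Inf, -2), d2 = c(-2, 2), d3 = c(-Inf, -2)),
      nonpriming = list(
        d1 = if (pdsi_d1_variant == "table") c(-2, 2) else c(0, 2),
        d2 = c(-2, 2), d3 = c(-Inf, -2)),
      control = list(d1 = c(-2, 2), d2 = c(-2, 2), d3 = c(-2, 2))),
    spa = list(
      priming = list(d1 = c(-2, -0.5), d2 = c(-0.5, 0.5), d3 = c(-2, -0.5)),
      nonpriming = list(d1 = c(-0.5, 0.5), d2 = c(-0.5, 0.5),
                        d3 = c(-2, -0.5)),
      control = list(d1 = c(-0.5, 0.5), d2 = c(-0.5, 0.5),
                     d3 = c(-0.5, 0.5))),
    sta = list(
      priming = list(d1 = c(0.5, 2), d2 = c(-0.5, 0.5), d3 = c(0.5, 2)),
      nonpriming = list(d1 = c(-0.5, 0.5), d2 = c(-0.5, 0.5),
                        d3 = c(0.5, 2)),
      control = list(d1 = c(-0.5, 0.5), d2 = c(-0.5, 0.5),
                     d3 = c(-0.5, 0.5))))
  for (g in c("priming", "nonpriming")) {
    stopifnot(identical(rules[[g]]$d2, rules$priming$d2),
              identical(rules[[g]]$d3, rules$priming$d3))
  }
  structure(c(list(index = index), rules), class = "group_rules")
}

in_window <- function(x, w) x > w[1] & x < w[2]

#' Assign priming/nonpriming/control labels to county-years
#'
#' Each county-year with all three durations present is tested against the
#' rule windows in the order priming, nonpriming, control; county-years
#' matching none (or missing a duration) are labelled `"excluded"`.
#'
#' @param duration_climate long table with `county_id`, `year`, `duration`
#'   and the index column (`pdsi`, `spa` or `sta`).
#' @param rules a `group_rules` from [default_group_rules()].
#' @return data.frame (`county_id`, `year`, `label`).
#' @export
assign_groups <- function(duration_climate, rules) {
  col <- rules$index
  if (!col %in% names(duration_climate))
    stop_primecrop(paste("duration climate lacks column", col),
                   "primecrop_input_error")
  wide <- stats::reshape(
    duration_climate[, c("county_id", "year", "duration", col)],
    direction = "wide", idvar = c("county_id", "year"),
    timevar = "duration", sep = "_")
  need <- paste(col, c("D1", "D2", "D3"), sep = "_")
  for (cc in setdiff(need, names(wide))) wide[[cc]] <- NA_real_
  v <- as.matrix(wide[, need])
  label <- rep("excluded", nrow(wide))
  complete <- apply(is.finite(v), 1, all)
  for (g in c("priming", "nonpriming", "control")) {
    w <- rules[[g]]
    hit <- complete & label == "excluded" &
      in_window(v[, 1], w$d1) & in_window(v[, 2], w$d2) &
      in_window(v[, 3], w$d3)
    label[hit] <- g
  }
  data.frame(county_id = wide$county_id, year = wide$year, label = label,
             stringsAsFactors = FALSE)
}

#' Mitigation arithmetic from group means
#'
#' mitigation_abs = mean(priming) - mean(nonpriming);
#' loss_nonpriming = mean(control) - mean(nonpriming);
#' mitigation_frac = mitigation_abs / loss_nonpriming (undefined when the
#' nonpriming loss is not positive); pct_of_mean_yield = 100 *
#' mitigation_abs / mean_yield.
#'
#' @param mean_control,mean_priming,mean_nonpriming group means of the
#'   response (yield anomaly or yield, Mg/Ha).
#' @param mean_yield optional mean yield (Mg/Ha) for the percent-of-yield
#'   figure.
#' @return list: `mitigation_abs`, `loss_nonpriming`, `mitigation_frac`,
#'   `pct_of_mean_yield` (NA without `mean_yield`), `note`.
#' @export
mitigation_metrics <- function(mean_control, mean_priming, mean_nonpriming,
                               mean_yield = NULL) {
  mitigation_abs <- mean_priming - mean_nonpriming
  loss_nonpriming <- mean_control - mean_nonpriming
  if (loss_nonpriming > 0) {
    mitigation_frac <- mitigation_abs / loss_nonpriming
    note <- NA_character_
  } else {
    mitigation_frac <- NA_real_
    note <- "nonpriming loss not positive; mitigation fraction undefined"
  }
  pct <- if (is.null(mean_yield)) NA_real_ else {
    if (mean_yield <= 0)
      stop_primecrop("mean_yield must be positive", "primecrop_input_error")
    100 * mitigation_abs / mean_yield
  }
  list(mitigation_abs = mitigation_abs, loss_nonpriming = loss_nonpriming,
       mitigation_frac = mitigation_frac, pct_of_mean_yield = pct,
       note = note)
}

#' Compare response values across priming groups
#'
#' Welch two-sample t-test of priming vs nonpriming, one-way ANOVA across
#' the three groups, per-group summary statistics and the mitigation metrics
#' derived from the group means.
#'
#' @param responses numeric response per county-year (a yield anomaly
#'   variant, raw yield, or simulated yield).
#' @param labels matching character labels (`"priming"`, `"nonpriming"`,
#'   `"control"`; other labels are ignored).
#' @param mean_yield optional mean yield for the percent-of-yield metric.
#' @return list of class `priming_result`: `groups` (n/mean/sd per group),
#'   `t_statistic`, `p_value`, `anova_f`, `anova_p`, and the
#'   [mitigation_metrics()] fields.
#' @export
compare_groups <- function(responses, labels, mean_yield = NULL) {
  stopifnot(length(responses) == length(labels))
  keep <- labels %in% c("priming", "nonpriming", "control") &
    is.finite(responses)
  responses <- responses[keep]; labels <- labels[keep]
  for (g in c("priming", "nonpriming", "control")) {
    if (sum(labels == g) < 2)
      stop_primecrop(paste("fewer than 2 observations in group", g),
                     "primecrop_insufficient_data")
  }
  groups <- do.call(rbind, lapply(c("control", "nonpriming", "priming"),
                                  function(g) {
    x <- responses[labels == g]
    data.frame(group = g, n = length(x), mean = mean(x), sd = stats::sd(x),
               stringsAsFactors = FALSE)
  }))
  tt <- stats::t.test(responses[labels == "priming"],
                      responses[labels == "nonpriming"])
  av <- summary(stats::aov(responses ~ factor(labels)))[[1]]
  mm <- mitigation_metrics(groups$mean[groups$group == "control"],
                           groups$mean[groups$group == "priming"],
                           groups$mean[groups$group == "nonpriming"],
                           mean_yield)
  structure(c(list(groups = groups,
                   t_statistic = unname(tt$statistic),
                   p_value = tt$p.value,
                   anova_f = av$`F value`[1], anova_p = av$`Pr(>F)`[1]),
              mm),
            class = "priming_result")
}

#' Count priming-labelled years per county
#'
#' @param labels data.frame (`county_id`, `label`).
#' @return data.frame (`county_id`, `n_priming`).
#' @export
county_priming_frequency <- function(labels) {
  counts <- tapply(labels$label == "priming", labels$county_id, sum)
  data.frame(county_id = names(counts), n_priming = as.integer(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' LAI summary statistics by group and duration
#'
#' Mean, median, SD and n of leaf area index per group x duration, with
#' Welch pairwise significance flags at the 0.05 level.
#'
#' @param lai data.frame (`county_id`, `year`, `duration`, `lai`).
#' @param labels data.frame (`county_id`, `year`, `label`).
#' @param alpha significance level for the pairwise flags.
#' @return list: `stats` (per group x duration) and `pairwise` (per duration
#'   and group pair: p-value and significance flag). Empty group x duration
#'   cells are omitted and listed in `omitted`.
#' @export
lai_group_stats <- function(lai, labels, alpha = 0.05) {
  if (any(lai$lai < 0))
    stop_primecrop("LAI values must be nonnegative", "primecrop_input_error")
  d <- merge(lai, labels, by = c("county_id", "year"))
  d <- d[d$label %in% c("priming", "nonpriming", "control"), ]
  omitted <- character(0)
  stats_rows <- list(); pair_rows <- list()
  for (dur in sort(unique(d$duration))) {
    dd <- d[d$duration == dur, ]
    for (g in c("control", "nonpriming", "priming")) {
      x <- dd$lai[dd$label == g]
      if (length(x) == 0) {
        omitted <- c(omitted, paste(g, dur))
        next
      }
      stats_rows[[paste(g, dur)]] <- data.frame(
        group = g, duration = dur, n = length(x), mean = mean(x),
        median = stats::median(x), sd = stats::sd(x),
        stringsAsFactors = FALSE)
    }
    prs <- utils::combn(c("control", "nonpriming", "priming"), 2)
    for (k in seq_len(ncol(prs))) {
      a <- dd$lai[dd$label == prs[1, k]]
      b <- dd$lai[dd$label == prs[2, k]]
      if (length(a) < 2 || length(b) < 2) next
      p <- tryCatch(stats::t.test(a, b)$p.value,
                    error = function(e) NA_real_)   # constant data
      if (is.na(p)) p <- 1
      pair_rows[[paste(dur, k)]] <- data.frame(
        duration = dur, group_a = prs[1, k], group_b = prs[2, k],
        p_value = p, significant = p < alpha, stringsAsFactors = FALSE)
    }
  }
  list(stats = do.call(rbind, c(stats_rows, list(make.row.names = FALSE))),
       pairwise = do.call(rbind, c(pair_rows, list(make.row.names = FALSE))),
       omitted = omitted)
}
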