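# Pharmacodynamic and performance endpoints: substance P percent change
# and log-log PK/PD regression, geometric-mean-ratio treatment contrast,
# lying-behavior aggregation and pre/post contrasts, average daily gain,
# and heart-rate pre/post means.
#
# The source study fit random-effects mixed models (repeated-measures
# endpoints) and a random-effects logistic regression (lying behavior) in
# commercial software. Here those are replaced by documented simplified
# contrasts -- pooled two-proportion z tests and t-based contrasts on the
# log scale. This is a stated fidelity limitation, not a claim of
# equivalence; see the methods vignette.

#' Percent change from the pre-dose baseline
#'
#' Maps each value to 100 (value - baseline)/baseline; the baseline point
#' itself maps to 0. Scale-invariant: multiplying the whole series by a
#' positive constant leaves the result unchanged.
#'
#' @param values Numeric endpoint series.
#' @param baseline_index Position of the pre-dose sample (default 1).
#' @return Numeric vector of percent changes.
#' @export
percent_change_from_baseline <- function(values, baseline_index = 1L) {
  if (baseline_index < 1L || baseline_index > length(values)) {
    abort_invalid_parameter("`baseline_index` out of range")
  }
  baseline <- values[baseline_index]
  if (!is.finite(baseline) || baseline <= 0) {
    abort_invalid_parameter("baseline value must be positive")
  }
  100 * (values - baseline) / baseline
}

#' Log-log regression of an endpoint change on drug concentration
#'
#' Ordinary least squares of log10(y) on log10(x), the standard
#' exposure-response screen for a biomarker such as substance P percent
#' change against plasma drug concentration. Only pairs with x > 0 and
#' y > 0 enter (the logarithm is undefined otherwise); excluded pairs are
#' counted in the result.
#'
#' @param x Drug concentrations.
#' @param y Endpoint values (e.g. percent changes from baseline).
#' @return A list of class `loglog_fit` with `slope`, `intercept`,
#'   `r_squared`, `slope_ci95` (length-2 vector), `n_points`,
#'   `n_excluded`.
#' @export
loglog_regression <- function(x, y) {
  if (length(x) != length(y)) abort_invalid_parameter("`x` and `y` lengths differ")
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  n <- sum(ok)
  if (n < 3L) {
    abort_insufficient_data(sprintf(
      "log-log regression needs >= 3 positive pairs, got %d", n))
  }
  lx <- log10(x[ok]); ly <- log10(y[ok])
  fit <- stats::lm(ly ~ lx)
  cf <- unname(stats::coef(fit))
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::resid(fit)^2) / sst
  # t-based slope interval computed directly (summary.lm warns on an
  # exactly collinear fit, which is a legitimate input here)
  se_slope <- sqrt(sum(stats::resid(fit)^2) / (n - 2) / sum((lx - mean(lx))^2))
  ci <- cf[2L] + c(-1, 1) * stats::qt(0.975, n - 2) * se_slope
  structure(
    list(slope = cf[2L], intercept = cf[1L], r_squared = r2,
         slope_ci95 = ci, n_points = n, n_excluded = length(x) - n),
    class = "loglog_fit"
  )
}

#' Geometric-mean ratio of two groups with a 95% confidence interval
#'
#' ratio = exp(mean(ln a) - mean(ln b)); the interval back-transforms the
#' pooled-variance t interval for the difference of log means. This is
#' the back-transformed treatment contrast used for log-normally
#' distributed endpoints such as substance P.
#'
#' @param a,b Positive numeric vectors, each n >= 2.
#' @return A list of class `group_contrast` with `ratio`, `ci95`,
#'   `log_scale_se`, `df`.
#' @export
geometric_mean_ratio <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort_insufficient_data("geometric-mean ratio needs n >= 2 per group")
  }
  if (any(a <= 0) || any(b <= 0)) {
    abort_invalid_parameter("all values must be positive for a log-scale contrast")
  }
  la <- log(a); lb <- log(b)
  na <- length(a); nb <- length(b)
  diff <- mean(la) - mean(lb)
  sp2 <- ((na - 1) * stats::var(la) + (nb - 1) * stats::var(lb)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tq <- stats::qt(0.975, df = na + nb - 2)
  structure(
    list(ratio = exp(diff),
         ci95 = exp(c(diff - tq * se, diff + tq * se)),
         log_scale_se = se,
         df = na + nb - 2),
    class = "group_contrast"
  )
}

#' Average daily gain before and after dehorning
#'
#' ADG_pre = (pre-dehorning weight - arrival weight)/days between those
#' weighings; ADG_post = (post-dehorning weight - pre-dehorning
#' weight)/days between those weighings.
#'
#' @param weights A data.frame with columns `weight_arrival`,
#'   `weight_pre`, `weight_post` (kg) and `days_pre`, `days_post` (> 0).
#' @return The input with `adg_pre` and `adg_post` columns (kg/day) added.
#' @export
adg <- function(weights) {
  need <- c("weight_arrival", "weight_pre", "weight_post", "days_pre", "days_post")
  if (!all(need %in% names(weights))) {
    abort_invalid_parameter(paste("weights need columns:", paste(need, collapse = ", ")))
  }
  if (any(weights$days_pre <= 0) || any(weights$days_post <= 0)) {
    abort_invalid_parameter("`days_pre` and `days_post` must be positive")
  }
  weights$adg_pre <- (weights$weight_pre - weights$weight_arrival) / weights$days_pre
  weights$adg_post <- (weights$weight_post - weights$weight_pre) / weights$days_post
  weights
}

check_behavior_frame <- function(hours) {
  need <- c("subject_id", "hour", "lying", "standing", "walking", "excluded")
  if (!all(need %in% names(hours))) {
    abort_invalid_parameter(paste("behavior data need columns:",
                                  paste(need, collapse = ", ")))
  }
  counts <- hours$lying + hours$standing + hours$walking
  if (any(hours$lying < 0 | hours$standing < 0 | hours$walking < 0)) {
    abort_invalid_parameter("behavior epoch counts must be non-negative")
  }
  if (any(counts > 720L)) {
    abort_invalid_parameter("an hour holds at most 720 five-second epochs")
  }
  invisible(hours)
}

#' Pooled lying proportion over a pre- or post-dehorning window
#'
#' Sums lying epochs over all non-excluded hours in the window and
#' divides by the total epochs, i.e. a weighted average of hourly
#' proportions with epoch-count weights. Hours flagged `excluded`
#' (human-intervention periods) contribute nothing.
#'
#' @param hours Data.frame of hourly epoch counts with columns
#'   `subject_id`, `hour` (relative to dehorning; negative = pre),
#'   `lying`, `standing`, `walking`, `excluded`.
#' @param window `"pre"` (hour < 0) or `"post"` (hour >= 0).
#' @return The pooled proportion of time spent lying.
#' @export
lying_proportion <- function(hours, window = c("pre", "post")) {
  window <- match.arg(window)
  check_behavior_frame(hours)
  sel <- if (window == "pre") hours$hour < 0 else hours$hour >= 0
  sel <- sel & !hours$excluded
  if (!any(sel)) abort_insufficient_data("no non-excluded hours in window")
  h <- hours[sel, , drop = FALSE]
  total <- sum(h$lying + h$standing + h$walking)
  if (total == 0) abort_insufficient_data("no epochs recorded in window")
  sum(h$lying) / total
}

#' Standing-minutes-per-day equivalent of a lying-proportion change
#'
#' (p_pre - p_post) x 1440 minutes: how many more minutes per day an
#' animal stands after dehorning than before. Antisymmetric in its
#' arguments.
#'
#' @param p_pre,p_post Lying proportions in `[0, 1]`.
#' @return Minutes per day (signed, not rounded).
#' @export
minutes_per_day_difference <- function(p_pre, p_post) {
  if (any(c(p_pre, p_post) < 0) || any(c(p_pre, p_post) > 1)) {
    abort_invalid_parameter("proportions must lie in [0, 1]")
  }
  (p_pre - p_post) * 1440
}

#' Pre/post-by-treatment contrast of lying behavior
#'
#' For each treatment group, pools epoch counts into pre- and
#' post-dehorning lying proportions, tests the within-group pre-vs-post
#' change with a two-proportion z test on the aggregated counts, and
#' reports the between-group difference-in-differences on the proportion
#' scale. Calves missing either window are dropped with a warning
#' (mirroring accelerometer loss).
#'
#' @param hours Behavior data.frame as in [lying_proportion()], plus a
#'   `treatment` column with exactly two levels.
#' @return A list of class `behavior_contrast` with `by_group`
#'   (data.frame: treatment, p_pre, p_post, p_value, minutes_per_day),
#'   `did` (difference-in-differences), `n_calves`, `dropped`.
#' @export
prepost_treatment_contrast <- function(hours) {
  check_behavior_frame(hours)
  if (!"treatment" %in% names(hours)) {
    abort_invalid_parameter("behavior data need a `treatment` column")
  }
  keep <- !hours$excluded
  h <- hours[keep, , drop = FALSE]
  # drop calves missing a window
  dropped <- character(0)
  for (id in unique(h$subject_id)) {
    hi <- h[h$subject_id == id, ]
    if (!any(hi$hour < 0) || !any(hi$hour >= 0)) {
      dropped <- c(dropped, as.character(id))
    }
  }
  if (length(dropped)) {
    warning(sprintf("dropping calves missing a behavior window: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
    h <- h[!h$subject_id %in% dropped, , drop = FALSE]
  }
  groups <- sort(unique(h$treatment))
  if (length(groups) != 2L) abort_invalid_parameter("exactly two treatment groups required")
  for (g in groups) {
    if (length(unique(h$subject_id[h$treatment == g])) < 2L) {
      abort_insufficient_data("each group needs >= 2 calves with both windows")
    }
  }
  rows <- lapply(groups, function(g) {
    hg <- h[h$treatment == g, ]
    pre <- hg$hour < 0
    tot <- c(sum(hg$lying[pre] + hg$standing[pre] + hg$walking[pre]),
             sum(hg$lying[!pre] + hg$standing[!pre] + hg$walking[!pre]))
    ly <- c(sum(hg$lying[pre]), sum(hg$lying[!pre]))
    p <- ly / tot
    pv <- if (p[1L] == p[2L]) 1 else
      suppressWarnings(stats::prop.test(ly, tot, correct = FALSE)$p.value)
    data.frame(treatment = g, p_pre = p[1L], p_post = p[2L], p_value = pv,
               minutes_per_day = minutes_per_day_difference(p[1L], p[2L]),
               stringsAsFactors = FALSE)
  })
  by_group <- do.call(rbind, rows)
  did <- (by_group$p_post[2L] - by_group$p_pre[2L]) -
         (by_group$p_post[1L] - by_group$p_pre[1L])
  structure(
    list(by_group = by_group, did = did,
         n_calves = length(unique(h$subject_id)), dropped = dropped),
    class = "behavior_contrast"
  )
}

#' Group mean heart rate before and after dehorning
#'
#' Per-calf means within each window first (missing samples skipped),
#' then the group mean and standard error across calves. Calves with an
#' empty window are excluded with a warning.
#'
#' @param hr Data.frame with columns `subject_id`, `treatment`, `time_h`
#'   (relative to dehorning) and `hr` (beats/minute; `NA` = missing).
#' @param dehorn_time Boundary between the pre and post windows (hours).
#' @return A data.frame with one row per treatment x window and columns
#'   `treatment`, `window`, `mean`, `se`, `n_calves`.
#' @export
hr_prepost_means <- function(hr, dehorn_time = 0) {
  need <- c("subject_id", "treatment", "time_h", "hr")
  if (!all(need %in% names(hr))) {
    abort_invalid_parameter(paste("heart-rate data need columns:",
                                  paste(need, collapse = ", ")))
  }
  rows <- list()
  for (g in sort(unique(hr$treatment))) {
    for (win in c("pre", "post")) {
      sel <- hr$treatment == g &
        (if (win == "pre") hr$time_h < dehorn_time else hr$time_h >= dehorn_time)
      hw <- hr[sel & !is.na(hr$hr), , drop = FALSE]
      means <- tapply(hw$hr, hw$subject_id, mean)
      ids_all <- unique(hr$subject_id[hr$treatment == g])
      missing <- setdiff(as.character(ids_all), names(means))
      if (length(missing)) {
        warning(sprintf("calves with no usable %s-window heart-rate data excluded: %s",
                        win, paste(missing, collapse = ", ")), call. = FALSE)
      }
      m <- as.numeric(means)
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = g, window = win, mean = mean(m),
        se = if (length(m) > 1L) stats::sd(m) / sqrt(length(m)) else NA_real_,
        n_calves = length(m), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
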