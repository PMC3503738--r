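# Seeded generator of complete synthetic study cohorts reproducing the
# trial design: 12 calves block-randomized in weight-matched pairs to a
# single 0.5 mg/kg IV meloxicam bolus or saline placebo immediately
# before scoop dehorning, with the study's blood-sampling schedule,
# accelerometer behavior epochs, heart-rate telemetry and weigh-ins.
#
# Reproducibility design: every endpoint x animal combination draws from
# its own RNG substream derived from the master seed, so adding or
# reordering endpoints never perturbs existing draws.

# The blood-sampling schedule, in hours: 0 (pre-dose), 5, 10, 15, 20,
# 30, 60 minutes, then 6, 22, 30, 45, 52 hours.
STUDY_SCHEDULE_H <- c(0, 5 / 60, 10 / 60, 15 / 60, 20 / 60, 0.5, 1, 6, 22, 30, 45, 52)

#' Study configuration for the synthetic cohort generator
#'
#' Defaults reproduce the trial's design and reported effect sizes:
#' 6 calves per arm, 500 ug/kg IV dose, the blood-sampling schedule,
#' population mean PK parameters from the fitted two-compartment model,
#' cortisol peaking 15 min after dehorning at ~160 nmol/L in both arms,
#' a substance P treated:control geometric-mean ratio of 0.5, lying
#' proportions 46.1% -> 42.7% (control) vs 43.1% -> 43.0% (treated), and
#' post-dehorning ADG 1.05 (treated) vs 0.40 (control) kg/day.
#'
#' @param seed Master RNG seed (integer).
#' @param n_per_group Calves per treatment arm.
#' @param dose_per_kg IV meloxicam dose, ug/kg.
#' @param sampling_schedule Blood-sampling times in hours.
#' @param pk_population_means `clearance_params` population means.
#' @param pk_bsv_cv Lognormal between-animal CV of the PK parameters.
#' @param residual_cv Proportional residual error CV on concentrations.
#' @param loq Assay limit of quantification, ug/mL.
#' @param cortisol_params List: `baseline` and `peak` (nmol/L),
#'   `peak_time` (h), `pulse_width` (log-time SD of the surge),
#'   `animal_cv`, `sample_cv`.
#' @param sp_params List: `control_geomean` (pg/mL), `treatment_ratio`,
#'   `animal_cv`, `sample_cv`.
#' @param hr_params List: `pre_mean` (bpm), `elevated_mean` (bpm over
#'   hours 0-6), `recovery_mean` (bpm over hours 6-12),
#'   `treated_dip` (bpm subtracted for the treated arm during
#'   `dip_hours`), `dip_hours`, `animal_sd`, `residual_sd`,
#'   `missing_frac`, `window_h` (pre/post recording span).
#' @param behavior_params List: `lying_pre` and `lying_post` (named
#'   per-arm probabilities), `walk_frac` (share of non-lying epochs spent
#'   walking), `pre_hours` (48), `post_hours` (168), `excluded_hours`
#'   (human-intervention hours, removed equally from both arms),
#'   `dropout` (emulate the loss of one treated calf's accelerometer).
#' @param weight_params List: `arrival_range` (kg), `adg_pre_mean`,
#'   `adg_pre_sd`, `adg_post_mean` (per arm), `adg_post_sd` (per arm),
#'   `days_pre` (19), `days_post` (10).
#' @return A list of class `study_config`.
#' @export
study_config <- function(
    seed = 20120901L,
    n_per_group = 6L,
    dose_per_kg = 500,
    sampling_schedule = STUDY_SCHEDULE_H,
    pk_population_means = clearance_params(vc = 94.88, cl = 6.64,
                                           cld2 = 225.18, v2 = 99.07),
    pk_bsv_cv = 0.20,
    residual_cv = 0.15,
    loq = 0.025,
    cortisol_params = list(baseline = 45, peak = 160, peak_time = 0.25,
                           pulse_width = 0.8, animal_cv = 0.15, sample_cv = 0.15),
    sp_params = list(control_geomean = 114.7, treatment_ratio = 0.5,
                     animal_cv = 0.45, sample_cv = 0.15),
    hr_params = list(pre_mean = 91, elevated_mean = 103, recovery_mean = 92,
                     treated_dip = 6, dip_hours = c(8, 10),
                     animal_sd = 9, residual_sd = 6,
                     missing_frac = 0.05, window_h = 48),
    behavior_params = list(
      lying_pre = c(control = 0.461, meloxicam = 0.431),
      lying_post = c(control = 0.427, meloxicam = 0.430),
      walk_frac = 0.05, pre_hours = 48L, post_hours = 168L,
      excluded_hours = c(-24L, 0L, 24L, 48L, 72L, 96L, 120L, 144L),
      dropout = TRUE),
    weight_params = list(arrival_range = c(140, 205),
                         adg_pre_mean = 0.9, adg_pre_sd = 0.3,
                         adg_post_mean = c(control = 0.40, meloxicam = 1.05),
                         adg_post_sd = c(control = 0.61, meloxicam = 0.32),
                         days_pre = 19, days_post = 10)) {
  if (n_per_group < 1L) abort_invalid_parameter("`n_per_group` must be >= 1")
  check_positive(dose_per_kg, "dose_per_kg")
  if (any(diff(sampling_schedule) <= 0)) {
    abort_invalid_parameter("`sampling_schedule` must be strictly increasing")
  }
  stopifnot(inherits(pk_population_means, "clearance_params"))
  if (pk_bsv_cv < 0 || residual_cv < 0) {
    abort_invalid_parameter("CVs must be >= 0")
  }
  pr <- c(behavior_params$lying_pre, behavior_params$lying_post)
  if (any(pr < 0 | pr > 1)) abort_invalid_parameter("lying probabilities must be in [0, 1]")
  structure(
    list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
         dose_per_kg = dose_per_kg, sampling_schedule = sampling_schedule,
         pk_population_means = pk_population_means, pk_bsv_cv = pk_bsv_cv,
         residual_cv = residual_cv, loq = loq,
         cortisol_params = cortisol_params, sp_params = sp_params,
         hr_params = hr_params, behavior_params = behavior_params,
         weight_params = weight_params),
    class = "study_config"
  )
}

# evaluate `expr` under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# deterministic substream seed: endpoint stream block + animal index,
# mixed with the master seed; kept within the 32-bit integer range
sub_seed <- function(master, stream, animal = 0L) {
  (as.double(master) * 48271 + stream * 259511 + animal * 7919) %% 2147483647
}

STREAMS <- c(weights_arrival = 1, randomize = 2, pk = 3, cortisol = 4,
             sp = 5, hr = 6, behavior = 7, weights_gain = 8)

# lognormal multiplier with geometric mean 1 and the given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))
}

#' Block randomization by weight-matched pairs
#'
#' Animals are ranked by ascending weight and paired consecutively; each
#' calf in a pair draws a uniform random number and the higher draw is
#' assigned to the meloxicam group, the lower to control. Exactly half
#' the animals end up in each arm.
#'
#' @param weights Body weights in kg (even count).
#' @param seed RNG seed.
#' @return Character vector of `"meloxicam"`/`"control"` in the original
#'   animal order.
#' @export
block_randomize <- function(weights, seed) {
  n <- length(weights)
  if (n %% 2L != 0L) abort_invalid_parameter("block randomization needs an even count")
  ord <- order(weights)
  assign <- character(n)
  with_seed(seed, {
    for (b in seq_len(n / 2L)) {
      pair <- ord[c(2L * b - 1L, 2L * b)]
      draws <- stats::runif(2L)
      assign[pair[which.max(draws)]] <- "meloxicam"
      assign[pair[which.min(draws)]] <- "control"
    }
  })
  assign
}

#' Simulate meloxicam plasma concentration profiles
#'
#' Treated animals draw per-animal clearance-family parameters
#' lognormally around the population means (geometric mean = typical
#' value) with CV `pk_bsv_cv`, then observe the two-compartment
#' prediction at the sampling schedule under proportional residual
#' error. The pre-dose sample and any value below the LOQ are flagged
#' BLOQ. Control animals are entirely BLOQ.
#'
#' @param cfg A `study_config`.
#' @param animals Data.frame with `subject_id` and `treatment`.
#' @return Named list of `concentration_profile` objects (one per
#'   animal), with attribute `true_params` holding each treated animal's
#'   generating `micro_params`.
#' @export
generate_pk_profiles <- function(cfg, animals) {
  d <- dose_regimen(cfg$dose_per_kg)
  tt <- cfg$sampling_schedule
  pm <- cfg$pk_population_means
  profiles <- list()
  true_params <- list()
  for (i in seq_len(nrow(animals))) {
    id <- animals$subject_id[i]
    trt <- animals$treatment[i]
    if (trt == "meloxicam") {
      drawn <- with_seed(sub_seed(cfg$seed, STREAMS[["pk"]], i), {
        mult <- rlnorm_cv(4L, cfg$pk_bsv_cv)
        pi <- clearance_params(vc = pm$vc * mult[1L], cl = pm$cl * mult[2L],
                               cld2 = pm$cld2 * mult[3L], v2 = pm$v2 * mult[4L])
        mi <- micro_from_clearance(pi)
        pred <- predict_conc_values(mi, d, tt)
        eps <- stats::rnorm(length(tt), 0, cfg$residual_cv)
        list(mi = mi, conc = pmax(pred * (1 + eps), 0))
      })
      conc <- drawn$conc
      conc[tt <= d$admin_time] <- 0  # pre-dose draw precedes the bolus
      bloq <- conc < cfg$loq | tt <= d$admin_time
      true_params[[as.character(id)]] <- drawn$mi
      prof <- concentration_profile(id, trt, "meloxicam", tt, conc,
                                    loq = cfg$loq, bloq = bloq)
    } else {
      prof <- concentration_profile(id, trt, "meloxicam", tt,
                                    rep(0, length(tt)), loq = cfg$loq,
                                    bloq = rep(TRUE, length(tt)))
    }
    profiles[[as.character(id)]] <- prof
  }
  attr(profiles, "true_params") <- true_params
  profiles
}

# smooth unimodal cortisol surge: baseline plus a log-time Gaussian bump
# peaking at `peak_time`; any smooth unimodal shape meeting the
# 10-30 min peak-window constraint would serve (shape is configuration,
# not science)
cortisol_mean_curve <- function(t, p) {
  delta <- 0.02
  bump <- exp(-(log((t + delta) / (p$peak_time + delta)))^2 / (2 * p$pulse_width^2))
  p$baseline + (p$peak - p$baseline) * bump
}

#' Simulate serum cortisol series
#'
#' Baseline-plus-pulse response to dehorning, identical in distribution
#' in both arms (the study found no treatment effect on cortisol), with
#' lognormal per-animal scale and per-sample noise.
#'
#' @inheritParams generate_pk_profiles
#' @return Data.frame with `subject_id`, `treatment`, `time_h`, `value`
#'   (nmol/L).
#' @export
generate_cortisol <- function(cfg, animals) {
  p <- cfg$cortisol_params
  tt <- cfg$sampling_schedule
  mu <- cortisol_mean_curve(tt, p)
  rows <- lapply(seq_len(nrow(animals)), function(i) {
    vals <- with_seed(sub_seed(cfg$seed, STREAMS[["cortisol"]], i), {
      scale_i <- rlnorm_cv(1L, p$animal_cv)
      mu * scale_i * rlnorm_cv(length(tt), p$sample_cv)
    })
    data.frame(subject_id = animals$subject_id[i],
               treatment = animals$treatment[i],
               time_h = tt, value = vals, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate plasma substance P series
#'
#' Lognormal values with no time trend; the treated arm's geometric mean
#' is the control geometric mean times `treatment_ratio`.
#'
#' @inheritParams generate_pk_profiles
#' @return Data.frame with `subject_id`, `treatment`, `time_h`, `value`
#'   (pg/mL).
#' @export
generate_sp <- function(cfg, animals) {
  p <- cfg$sp_params
  tt <- cfg$sampling_schedule
  rows <- lapply(seq_len(nrow(animals)), function(i) {
    gm_arm <- p$control_geomean *
      if (animals$treatment[i] == "meloxicam") p$treatment_ratio else 1
    vals <- with_seed(sub_seed(cfg$seed, STREAMS[["sp"]], i), {
      gm_i <- gm_arm * rlnorm_cv(1L, p$animal_cv)
      gm_i * rlnorm_cv(length(tt), p$sample_cv)
    })
    data.frame(subject_id = animals$subject_id[i],
               treatment = animals$treatment[i],
               time_h = tt, value = vals, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

hr_mean_at <- function(t, trt, p) {
  mu <- ifelse(t < 0, p$pre_mean,
        ifelse(t < 6, p$elevated_mean,
        ifelse(t < 12, p$recovery_mean, p$pre_mean)))
  if (trt == "meloxicam") {
    in_dip <- Reduce(`|`, lapply(p$dip_hours, function(h) t >= h & t < h + 1))
    mu <- mu - p$treated_dip * in_dip
  }
  mu
}

#' Simulate heart-rate telemetry
#'
#' 15-second sampled series over the recording window on each side of
#' dehorning: elevated over the first 6 h in both arms, with the treated
#' arm dipping at the configured hours (8 and 10 by default), per-animal
#' random level, residual noise and random missingness.
#'
#' @inheritParams generate_pk_profiles
#' @return Data.frame with `subject_id`, `treatment`, `time_h`, `hr`
#'   (bpm; `NA` where the telemetry dropped out).
#' @export
generate_hr <- function(cfg, animals) {
  p <- cfg$hr_params
  tt <- seq(-p$window_h, p$window_h, by = 15 / 3600)
  rows <- lapply(seq_len(nrow(animals)), function(i) {
    trt <- animals$treatment[i]
    mu <- hr_mean_at(tt, trt, p)
    vals <- with_seed(sub_seed(cfg$seed, STREAMS[["hr"]], i), {
      level <- stats::rnorm(1L, 0, p$animal_sd)
      v <- mu + level + stats::rnorm(length(tt), 0, p$residual_sd)
      if (p$missing_frac > 0) {
        v[stats::runif(length(tt)) < p$missing_frac] <- NA_real_
      }
      v
    })
    data.frame(subject_id = animals$subject_id[i], treatment = trt,
               time_h = tt, hr = vals, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate hourly accelerometer behavior counts
#'
#' For each calf and hour, the lying count is binomial over 720
#' five-second epochs with the arm- and window-specific probability;
#' the non-lying remainder is split between standing and walking.
#' Configured human-intervention hours are flagged excluded in both arms
#' alike, and (optionally) one treated calf's record is removed to
#' emulate an accelerometer failure.
#'
#' @inheritParams generate_pk_profiles
#' @return Data.frame with `subject_id`, `treatment`, `hour` (relative
#'   to dehorning), `lying`, `standing`, `walking`, `excluded`, plus a
#'   `dropout_id` attribute naming the removed calf (or `NULL`).
#' @export
generate_behavior <- function(cfg, animals) {
  p <- cfg$behavior_params
  hours <- seq.int(-p$pre_hours, p$post_hours - 1L)
  rows <- lapply(seq_len(nrow(animals)), function(i) {
    trt <- animals$treatment[i]
    prob <- ifelse(hours < 0, p$lying_pre[[trt]], p$lying_post[[trt]])
    with_seed(sub_seed(cfg$seed, STREAMS[["behavior"]], i), {
      lying <- stats::rbinom(length(hours), 720L, prob)
      walking <- stats::rbinom(length(hours), 720L - lying, p$walk_frac)
      data.frame(subject_id = animals$subject_id[i], treatment = trt,
                 hour = hours, lying = lying,
                 standing = 720L - lying - walking, walking = walking,
                 excluded = hours %in% p$excluded_hours,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  dropout_id <- NULL
  if (isTRUE(p$dropout)) {
    treated <- animals$subject_id[animals$treatment == "meloxicam"]
    if (length(treated)) {
      dropout_id <- treated[1L]
      out <- out[out$subject_id != dropout_id, , drop = FALSE]
    }
  }
  attr(out, "dropout_id") <- dropout_id
  out
}

#' Simulate the three weigh-ins
#'
#' Arrival weights are uniform on the configured range; the
#' pre-dehorning weight adds `days_pre` days of normally drawn pre-study
#' gain, and the post-dehorning weight adds `days_post` days of
#' arm-specific gain.
#'
#' @inheritParams generate_pk_profiles
#' @param arrival Optional arrival weights (kg); drawn if omitted.
#' @return Data.frame with `subject_id`, `treatment`, `weight_arrival`,
#'   `weight_pre`, `weight_post`, `days_pre`, `days_post`.
#' @export
generate_weights <- function(cfg, animals, arrival = NULL) {
  p <- cfg$weight_params
  n <- nrow(animals)
  if (is.null(arrival)) {
    arrival <- with_seed(sub_seed(cfg$seed, STREAMS[["weights_arrival"]]),
                         stats::runif(n, p$arrival_range[1L], p$arrival_range[2L]))
  }
  gains <- with_seed(sub_seed(cfg$seed, STREAMS[["weights_gain"]]), {
    pre <- stats::rnorm(n, p$adg_pre_mean, p$adg_pre_sd)
    post <- vapply(seq_len(n), function(i) {
      trt <- animals$treatment[i]
      stats::rnorm(1L, p$adg_post_mean[[trt]], p$adg_post_sd[[trt]])
    }, numeric(1))
    list(pre = pre, post = post)
  })
  data.frame(subject_id = animals$subject_id,
             treatment = animals$treatment,
             weight_arrival = arrival,
             weight_pre = arrival + gains$pre * p$days_pre,
             weight_post = arrival + gains$pre * p$days_pre +
               gains$post * p$days_post,
             days_pre = p$days_pre, days_post = p$days_post,
             stringsAsFactors = FALSE)
}

#' Simulate one complete study cohort
#'
#' Draws arrival weights, block-randomizes weight-matched pairs, and
#' generates every endpoint table the analysis stages consume.
#'
#' @param cfg A `study_config`.
#' @param endpoints Which endpoint tables to generate (all by default);
#'   any subset of `"pk"`, `"cortisol"`, `"sp"`, `"hr"`, `"behavior"`,
#'   `"weights"`.
#' @return A list of class `synthetic_cohort` with `animals`, `pk`,
#'   `cortisol`, `sp`, `hr`, `behavior`, `weights` and `config`.
#' @export
simulate_cohort <- function(cfg = study_config(),
                            endpoints = c("pk", "cortisol", "sp", "hr",
                                          "behavior", "weights")) {
  stopifnot(inherits(cfg, "study_config"))
  endpoints <- match.arg(endpoints, several.ok = TRUE)
  n <- 2L * cfg$n_per_group
  p <- cfg$weight_params
  arrival <- with_seed(sub_seed(cfg$seed, STREAMS[["weights_arrival"]]),
                       stats::runif(n, p$arrival_range[1L], p$arrival_range[2L]))
  treatment <- block_randomize(arrival, sub_seed(cfg$seed, STREAMS[["randomize"]]))
  animals <- data.frame(subject_id = sprintf("calf_%02d", seq_len(n)),
                        treatment = treatment,
                        weight_arrival = arrival,
                        stringsAsFactors = FALSE)
  out <- list(animals = animals, config = cfg)
  if ("pk" %in% endpoints) out$pk <- generate_pk_profiles(cfg, animals)
  if ("cortisol" %in% endpoints) out$cortisol <- generate_cortisol(cfg, animals)
  if ("sp" %in% endpoints) out$sp <- generate_sp(cfg, animals)
  if ("hr" %in% endpoints) out$hr <- generate_hr(cfg, animals)
  if ("behavior" %in% endpoints) out$behavior <- generate_behavior(cfg, animals)
  if ("weights" %in% endpoints) {
    out$weights <- generate_weights(cfg, animals, arrival = arrival)
  }
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d calves (%d per arm), seed %d; endpoints: %s\n",
              nrow(x$animals), x$config$n_per_group, x$config$seed,
              paste(intersect(c("pk", "cortisol", "sp", "hr", "behavior", "weights"),
                              names(x)), collapse = ", ")))
  invisible(x)
}
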