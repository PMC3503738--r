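# Synthetic cohort generator: design properties, determinism, noise-off
# inversion through the analysis stages.

test_that("block randomization splits each weight-matched pair across arms", {
  set.seed(33)
  w <- runif(12, 140, 205)
  assign <- block_randomize(w, seed = 99)
  expect_equal(sum(assign == "meloxicam"), 6)
  expect_equal(sum(assign == "control"), 6)
  ord <- order(w)
  for (b in 1:6) {
    pair <- assign[ord[c(2 * b - 1, 2 * b)]]
    expect_setequal(pair, c("meloxicam", "control"))
  }
  # two animals, determinism, odd-count error
  expect_setequal(block_randomize(c(150, 160), seed = 1),
                  c("meloxicam", "control"))
  expect_identical(block_randomize(w, seed = 99), assign)
  expect_error(block_randomize(w[1:11], seed = 1),
               class = "calfpkpd_invalid_parameter")
})

test_that("identical config and seed give an identical cohort", {
  a <- simulate_cohort(study_config(seed = 314))
  b <- simulate_cohort(study_config(seed = 314))
  expect_identical(a, b)
  c2 <- simulate_cohort(study_config(seed = 315))
  expect_false(identical(a$weights$weight_post, c2$weights$weight_post))
})

test_that("endpoint substreams are independent of which endpoints are generated", {
  full <- simulate_cohort(study_config(seed = 27))
  sp_only <- simulate_cohort(study_config(seed = 27), endpoints = "sp")
  expect_identical(full$sp, sp_only$sp)
  wt_only <- simulate_cohort(study_config(seed = 27), endpoints = "weights")
  expect_identical(full$weights, wt_only$weights)
})

test_that("noise-off PK profiles equal the population-mean prediction", {
  cfg <- study_config(seed = 5, pk_bsv_cv = 0, residual_cv = 0)
  pk <- generate_pk_profiles(cfg, toy_animals())
  d <- dose_regimen(cfg$dose_per_kg)
  mi <- micro_from_clearance(cfg$pk_population_means)
  expected <- predict_concentration(mi, d, cfg$sampling_schedule)$concentrations
  treated <- Filter(function(p) any(!p$bloq), pk)
  expect_length(treated, 6)
  for (p in treated) {
    post <- p$times > 0
    expect_equal(p$concentrations[post], expected[post], tolerance = 1e-12)
    expect_true(p$bloq[1L])  # pre-dose draw
  }
  # fitting the noise-off profile recovers the generating parameters
  fit <- fit_compartmental(treated[[1L]], d, 2)
  expect_rel_equal(unlist(fit$params), unlist(mi), 0.001)
})

test_that("control animals have no quantifiable meloxicam", {
  pk <- generate_pk_profiles(study_config(seed = 6), toy_animals())
  controls <- pk[vapply(pk, function(p) p$treatment == "control", logical(1))]
  expect_length(controls, 6)
  for (p in controls) expect_true(all(p$bloq))
})

test_that("cortisol pulse peaks at the configured time and flattens without one", {
  cfg <- study_config(seed = 8,
                      cortisol_params = list(baseline = 45, peak = 160,
                                             peak_time = 0.25, pulse_width = 0.8,
                                             animal_cv = 0, sample_cv = 0))
  cort <- generate_cortisol(cfg, toy_animals(1))
  one <- cort[cort$subject_id == "calf_01", ]
  expect_equal(one$time_h[which.max(one$value)], 0.25)
  expect_equal(max(one$value), 160, tolerance = 1e-9)
  expect_lt(one$value[one$time_h == 52], 46)

  flat_cfg <- study_config(seed = 8,
                           cortisol_params = list(baseline = 45, peak = 45,
                                                  peak_time = 0.25, pulse_width = 0.8,
                                                  animal_cv = 0, sample_cv = 0))
  flat <- generate_cortisol(flat_cfg, toy_animals(1))
  expect_equal(flat$value, rep(45, nrow(flat)), tolerance = 1e-12)
})

test_that("cortisol peak height is recovered across a large sample of animals", {
  cfg <- study_config(seed = 9)
  many <- data.frame(subject_id = sprintf("x%03d", 1:200),
                     treatment = rep(c("meloxicam", "control"), 100),
                     stringsAsFactors = FALSE)
  cort <- generate_cortisol(cfg, many)
  cmaxes <- tapply(cort$value, cort$subject_id, max)
  # observed Cmax sits near the configured 160 nmol/L pulse height
  # (slightly above it: the maximum of noisy samples is upward-biased)
  expect_gt(mean(cmaxes), 160 * 0.9)
  expect_lt(mean(cmaxes), 160 * 1.25)
})

test_that("substance P reproduces the configured geometric-mean ratio", {
  cfg <- study_config(seed = 12,
                      sp_params = list(control_geomean = 114.7,
                                       treatment_ratio = 0.5,
                                       animal_cv = 0, sample_cv = 0))
  sp <- generate_sp(cfg, toy_animals())
  gm <- tapply(sp$value, sp$subject_id, function(v) exp(mean(log(v))))
  trt <- tapply(sp$treatment, sp$subject_id, `[`, 1L)
  expect_equal(as.numeric(gm[trt == "control"]), rep(114.7, 6), tolerance = 1e-9)
  expect_equal(as.numeric(gm[trt == "meloxicam"]), rep(114.7 * 0.5, 6),
               tolerance = 1e-9)

  # ratio 1.0 with noise: the contrast interval covers 1
  cfg1 <- study_config(seed = 13,
                       sp_params = list(control_geomean = 114.7,
                                        treatment_ratio = 1,
                                        animal_cv = 0.45, sample_cv = 0.15))
  sp1 <- generate_sp(cfg1, toy_animals())
  gm1 <- tapply(sp1$value, sp1$subject_id, function(v) exp(mean(log(v))))
  trt1 <- tapply(sp1$treatment, sp1$subject_id, `[`, 1L)
  g <- geometric_mean_ratio(gm1[trt1 == "meloxicam"], gm1[trt1 == "control"])
  expect_lt(g$ci95[1], 1)
  expect_gt(g$ci95[2], 1)
})

test_that("heart-rate series honor the configured pre/post structure", {
  noiseless <- list(pre_mean = 91, elevated_mean = 103, recovery_mean = 92,
                    treated_dip = 6, dip_hours = c(8, 10),
                    animal_sd = 0, residual_sd = 0,
                    missing_frac = 0, window_h = 12)
  cfg <- study_config(seed = 14, hr_params = noiseless)
  hr <- generate_hr(cfg, toy_animals(1))
  ctl <- hr[hr$treatment == "control", ]
  trt <- hr[hr$treatment == "meloxicam", ]
  expect_equal(unique(ctl$hr[ctl$time_h < 0]), 91)
  expect_equal(unique(ctl$hr[ctl$time_h >= 0 & ctl$time_h < 6]), 103)
  # treated arm dips during hours 8 and 10 only
  expect_equal(unique(trt$hr[trt$time_h >= 8 & trt$time_h < 9]), 92 - 6)
  expect_equal(unique(trt$hr[trt$time_h >= 9 & trt$time_h < 10]), 92)
  sm <- hr_prepost_means(hr)
  expect_equal(sm$mean[sm$treatment == "control" & sm$window == "pre"], 91)

  # full missingness excludes the calf downstream with a warning
  all_miss <- noiseless
  all_miss$missing_frac <- 1
  hr2 <- generate_hr(study_config(seed = 15, hr_params = all_miss), toy_animals(1))
  expect_true(all(is.na(hr2$hr)))
  w <- capture_warnings(hr_prepost_means(hr2))
  expect_true(any(grepl("excluded", w)))
})

test_that("behavior counts follow the configured lying probabilities", {
  cfg <- study_config(seed = 16)
  bp <- cfg$behavior_params
  bp$lying_pre <- c(control = 1, meloxicam = 1)
  bp$lying_post <- c(control = 1, meloxicam = 1)
  bp$dropout <- FALSE
  all_lie <- generate_behavior(study_config(seed = 16, behavior_params = bp),
                               toy_animals(1))
  expect_true(all(all_lie$lying == 720))

  beh <- generate_behavior(cfg, toy_animals())
  # default dropout removes exactly one treated calf
  expect_length(unique(beh$subject_id), 11)
  expect_equal(attr(beh, "dropout_id"), "calf_01")
  expect_false(attr(beh, "dropout_id") %in% beh$subject_id)
  # pooled proportions sit near the configured probabilities
  ctl <- beh[beh$treatment == "control", ]
  expect_equal(lying_proportion(ctl, "pre"), 0.461, tolerance = 0.01)
  expect_equal(lying_proportion(ctl, "post"), 0.427, tolerance = 0.01)
  # configured intervention hours are flagged for every calf
  expect_true(all(beh$excluded[beh$hour == 0]))
  expect_true(all(!beh$excluded[beh$hour == 1]))
})

test_that("weigh-ins invert exactly through the ADG stage when noise-free", {
  wp <- list(arrival_range = c(140, 205),
             adg_pre_mean = 0.9, adg_pre_sd = 0,
             adg_post_mean = c(control = 0.40, meloxicam = 1.05),
             adg_post_sd = c(control = 0, meloxicam = 0),
             days_pre = 19, days_post = 10)
  w <- generate_weights(study_config(seed = 17, weight_params = wp), toy_animals())
  out <- adg(w)
  expect_equal(out$adg_pre, rep(0.9, 12), tolerance = 1e-12)
  expect_equal(out$adg_post[out$treatment == "meloxicam"], rep(1.05, 6),
               tolerance = 1e-12)
  expect_equal(out$adg_post[out$treatment == "control"], rep(0.40, 6),
               tolerance = 1e-12)

  wp0 <- wp
  wp0$adg_pre_mean <- 0
  wp0$adg_post_mean <- c(control = 0, meloxicam = 0)
  w0 <- generate_weights(study_config(seed = 17, weight_params = wp0), toy_animals())
  expect_equal(w0$weight_arrival, w0$weight_pre)
  expect_equal(w0$weight_pre, w0$weight_post)
})

test_that("the simulated cohort has the study's shape", {
  co <- simulate_cohort(study_config(seed = 18))
  expect_equal(nrow(co$animals), 12)
  expect_equal(sum(co$animals$treatment == "meloxicam"), 6)
  expect_true(all(co$animals$weight_arrival >= 140 &
                    co$animals$weight_arrival <= 205))
  expect_length(co$pk, 12)
  expect_setequal(unique(co$sp$subject_id), co$animals$subject_id)
  expect_setequal(unique(co$cortisol$time_h), co$config$sampling_schedule)
  expect_equal(nrow(co$weights), 12)
})
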