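# Shared fixtures: the reported population mean parameters and study design.

# blood-sampling schedule in hours
schedule_h <- c(0, 5 / 60, 10 / 60, 15 / 60, 20 / 60, 0.5, 1, 6, 22, 30, 45, 52)

study_dose <- function() dose_regimen(500)

# reported population means, clearance family (mL/kg, mL/h/kg)
table1_clearance <- function() clearance_params(vc = 94.88, cl = 6.64,
                                                cld2 = 225.18, v2 = 99.07)

# reported population means, micro-rate family (1/h); the published
# per-family means were averaged independently, so this set is not the
# algebraic image of the clearance set
table1_micro <- function() micro_params(vc = 94.88, k10 = 0.075,
                                        k12 = 2.70, k21 = 2.20)

# random positive micro parameter set in a physiologic-ish range
random_micro <- function() {
  micro_params(vc = runif(1, 30, 300),
               k10 = runif(1, 0.01, 0.5),
               k12 = runif(1, 0.1, 5),
               k21 = runif(1, 0.1, 5))
}

# noise-free model profile at the study schedule
noise_free_profile <- function(p, d = study_dose(), times = schedule_h) {
  predict_concentration(p, d, times)
}

# tiny cohort animal table without running the full generator
toy_animals <- function(n_per_arm = 6) {
  data.frame(subject_id = sprintf("calf_%02d", seq_len(2 * n_per_arm)),
             treatment = rep(c("meloxicam", "control"), n_per_arm),
             stringsAsFactors = FALSE)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * abs(expected)),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(actual - expected) / abs(expected)), tol))
}
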