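# Closed-form one- and two-compartment IV-bolus models.
#
# Canonical internal units throughout the package: time in hours,
# concentration in ug/mL, volumes in mL/kg, dose in ug/kg. The clinical
# 0.5 mg/kg label dose is converted once, at the boundary (500 ug/kg).
# The canonical parameterization is the micro-rate-constant set
# (Vc, k10, k12, k21); the clearance and macro families are views of it.

#' IV-bolus dose regimen
#'
#' @param dose_per_kg Dose normalised to body weight, in ug/kg. The study
#'   dose of 0.5 mg/kg is the default (500 ug/kg).
#' @param admin_time Administration time in hours (an IV bolus at time 0).
#' @return An object of class `dose_regimen`.
#' @export
dose_regimen <- function(dose_per_kg = 500, admin_time = 0) {
  check_positive(dose_per_kg, "dose_per_kg")
  if (!is.numeric(admin_time) || length(admin_time) != 1L || !is.finite(admin_time)) {
    abort_invalid_parameter("`admin_time` must be a single finite number")
  }
  structure(
    list(dose_per_kg = dose_per_kg, route = "IV bolus", admin_time = admin_time),
    class = "dose_regimen"
  )
}

#' Micro-rate-constant parameterization of the two-compartment model
#'
#' @param vc Central volume of distribution (mL/kg).
#' @param k10 Elimination rate constant from the central compartment (1/h).
#' @param k12,k21 Central-to-peripheral and peripheral-to-central
#'   distribution rate constants (1/h).
#' @return An object of class `micro_params`.
#' @export
micro_params <- function(vc, k10, k12, k21) {
  check_positive(vc, "vc")
  check_positive(k10, "k10")
  check_positive(k12, "k12")
  check_positive(k21, "k21")
  structure(list(vc = vc, k10 = k10, k12 = k12, k21 = k21),
            class = c("micro_params", "pk_params"))
}

#' Clearance-volume parameterization of the two-compartment model
#'
#' @param vc Central volume (mL/kg).
#' @param cl Total body clearance (mL/h/kg).
#' @param cld2 Distributional (inter-compartmental) clearance (mL/h/kg).
#' @param v2 Peripheral volume (mL/kg).
#' @return An object of class `clearance_params`.
#' @export
clearance_params <- function(vc, cl, cld2, v2) {
  check_positive(vc, "vc")
  check_positive(cl, "cl")
  check_positive(cld2, "cld2")
  check_positive(v2, "v2")
  structure(list(vc = vc, cl = cl, cld2 = cld2, v2 = v2),
            class = c("clearance_params", "pk_params"))
}

#' Macro (bi-exponential) constants A, B, alpha, beta
#'
#' Houses the coefficients and exponents of the bolus solution
#' C(t) = A e^(-alpha t) + B e^(-beta t), with alpha > beta > 0.
#'
#' @param coef_a,coef_b Coefficients of the distribution and elimination
#'   exponentials (ug/mL); both non-negative.
#' @param alpha,beta Hybrid rate constants (1/h) of the distribution and
#'   elimination phases.
#' @return An object of class `macro_params`.
#' @export
macro_params <- function(coef_a, coef_b, alpha, beta) {
  if (!is.numeric(coef_a) || coef_a < 0 || !is.finite(coef_a)) {
    abort_invalid_parameter("`coef_a` must be finite and >= 0")
  }
  if (!is.numeric(coef_b) || coef_b < 0 || !is.finite(coef_b)) {
    abort_invalid_parameter("`coef_b` must be finite and >= 0")
  }
  check_positive(alpha, "alpha")
  check_positive(beta, "beta")
  if (alpha <= beta) abort_invalid_parameter("`alpha` must exceed `beta`")
  structure(list(coef_a = coef_a, coef_b = coef_b, alpha = alpha, beta = beta),
            class = c("macro_params", "pk_params"))
}

#' One-compartment IV-bolus parameters
#'
#' Candidate model for AIC/SBC model-order selection.
#'
#' @param v Volume of distribution (mL/kg).
#' @param k First-order elimination rate (1/h).
#' @return An object of class `one_comp_params`.
#' @export
one_comp_params <- function(v, k) {
  check_positive(v, "v")
  check_positive(k, "k")
  structure(list(v = v, k = k), class = c("one_comp_params", "pk_params"))
}

#' One animal's analyte concentration-time course
#'
#' @param subject_id,treatment,analyte Labels.
#' @param times Sampling times in hours; strictly increasing, >= 0.
#' @param concentrations Measured values (ug/mL for meloxicam); >= 0.
#' @param loq Assay limit of quantification in the analyte's units.
#' @param bloq Logical flags marking below-LOQ observations; defaults to
#'   `concentrations < loq`.
#' @return An object of class `concentration_profile`.
#' @export
concentration_profile <- function(subject_id, treatment, analyte,
                                  times, concentrations,
                                  loq = 0, bloq = NULL) {
  if (length(times) != length(concentrations)) {
    abort_invalid_parameter("`times` and `concentrations` must have equal length")
  }
  if (length(times) && (any(!is.finite(times)) || any(times < 0))) {
    abort_invalid_parameter("`times` must be finite and >= 0")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    abort_invalid_parameter("`times` must be strictly increasing")
  }
  if (length(concentrations) && any(!is.finite(concentrations) | concentrations < 0)) {
    abort_invalid_parameter("`concentrations` must be finite and >= 0")
  }
  if (!is.numeric(loq) || length(loq) != 1L || loq < 0) {
    abort_invalid_parameter("`loq` must be a single number >= 0")
  }
  if (is.null(bloq)) bloq <- concentrations < loq
  if (length(bloq) != length(times) || !is.logical(bloq)) {
    abort_invalid_parameter("`bloq` must be a logical vector matching `times`")
  }
  structure(
    list(subject_id = subject_id, treatment = treatment, analyte = analyte,
         times = as.numeric(times), concentrations = as.numeric(concentrations),
         loq = loq, bloq = bloq),
    class = "concentration_profile"
  )
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("<concentration_profile> %s / %s / %s: %d samples (%d BLOQ), LOQ %g\n",
              x$subject_id, x$treatment, x$analyte,
              length(x$times), sum(x$bloq), x$loq))
  invisible(x)
}

#' Convert clearance-volume parameters to micro-rate constants
#'
#' k10 = CL/Vc, k12 = CLD2/Vc, k21 = CLD2/V2.
#'
#' @param p A `clearance_params` object.
#' @return A `micro_params` object.
#' @export
micro_from_clearance <- function(p) {
  stopifnot(inherits(p, "clearance_params"))
  micro_params(vc = p$vc,
               k10 = p$cl / p$vc,
               k12 = p$cld2 / p$vc,
               k21 = p$cld2 / p$v2)
}

#' Convert micro-rate constants to clearance-volume parameters
#'
#' CL = k10 Vc, CLD2 = k12 Vc, V2 = k12 Vc / k21.
#'
#' @param p A `micro_params` object.
#' @return A `clearance_params` object.
#' @export
clearance_from_micro <- function(p) {
  stopifnot(inherits(p, "micro_params"))
  clearance_params(vc = p$vc,
                   cl = p$k10 * p$vc,
                   cld2 = p$k12 * p$vc,
                   v2 = p$k12 * p$vc / p$k21)
}

#' Hybrid macro constants of the bi-exponential bolus solution
#'
#' alpha and beta satisfy alpha + beta = k10 + k12 + k21 and
#' alpha * beta = k10 * k21 (alpha the larger root);
#' A = (D/Vc)(alpha - k21)/(alpha - beta), B = (D/Vc)(k21 - beta)/(alpha - beta).
#'
#' @param p A `micro_params` object.
#' @param d A `dose_regimen`.
#' @return A `macro_params` object.
#' @export
macro_from_micro <- function(p, d) {
  stopifnot(inherits(p, "micro_params"), inherits(d, "dose_regimen"))
  s <- p$k10 + p$k12 + p$k21
  q <- p$k10 * p$k21
  disc <- s * s - 4 * q
  if (disc <= 0) {
    # impossible for positive distinct rate constants; guard anyway
    abort_internal("degenerate roots (alpha == beta) in macro conversion")
  }
  alpha <- (s + sqrt(disc)) / 2
  beta <- q / alpha  # numerically stable companion root
  c0 <- d$dose_per_kg / p$vc
  coef_a <- c0 * (alpha - p$k21) / (alpha - beta)
  coef_b <- c0 * (p$k21 - beta) / (alpha - beta)
  macro_params(coef_a = max(coef_a, 0), coef_b = max(coef_b, 0),
               alpha = alpha, beta = beta)
}

#' Micro-rate constants from macro constants
#'
#' Inverse of [macro_from_micro()]: Vc = D/(A+B),
#' k21 = (A beta + B alpha)/(A + B), k10 = alpha beta / k21,
#' k12 = alpha + beta - k10 - k21.
#'
#' @param m A `macro_params` object.
#' @param d A `dose_regimen`.
#' @return A `micro_params` object.
#' @export
micro_from_macro <- function(m, d) {
  stopifnot(inherits(m, "macro_params"), inherits(d, "dose_regimen"))
  tot <- m$coef_a + m$coef_b
  if (tot <= 0) abort_invalid_parameter("coef_a + coef_b must be positive")
  vc <- d$dose_per_kg / tot
  k21 <- (m$coef_a * m$beta + m$coef_b * m$alpha) / tot
  k10 <- m$alpha * m$beta / k21
  k12 <- m$alpha + m$beta - k10 - k21
  micro_params(vc = vc, k10 = k10, k12 = max(k12, .Machine$double.eps),
               k21 = k21)
}

#' Predict the IV-bolus concentration-time curve
#'
#' Two-compartment: C(t) = A e^(-alpha t) + B e^(-beta t);
#' one-compartment: C(t) = (D/V) e^(-k t). C(0) = D/Vc in both cases.
#'
#' @param p A `micro_params` or `one_comp_params` object.
#' @param d A `dose_regimen`.
#' @param times Times (hours) at which to evaluate; must be >= 0.
#' @param subject_id,treatment,analyte,loq Metadata for the returned profile.
#' @return A `concentration_profile` of model-predicted values.
#' @export
predict_concentration <- function(p, d, times,
                                  subject_id = "model", treatment = "meloxicam",
                                  analyte = "meloxicam", loq = 0) {
  stopifnot(inherits(d, "dose_regimen"))
  if (any(!is.finite(times)) || any(times < 0)) {
    abort_invalid_parameter("`times` must be finite and >= 0")
  }
  conc <- predict_conc_values(p, d, times)
  concentration_profile(subject_id, treatment, analyte,
                        times = times, concentrations = conc, loq = loq)
}

# bare numeric prediction used by the fitter (no profile overhead)
predict_conc_values <- function(p, d, times) {
  if (inherits(p, "micro_params")) {
    m <- macro_from_micro(p, d)
    m$coef_a * exp(-m$alpha * times) + m$coef_b * exp(-m$beta * times)
  } else if (inherits(p, "one_comp_params")) {
    (d$dose_per_kg / p$v) * exp(-p$k * times)
  } else {
    abort_invalid_parameter("`p` must be micro_params or one_comp_params")
  }
}

#' Derived (secondary) pharmacokinetic parameters
#'
#' Vss = Vc (1 + k12/k21) = Vc + V2; T1/2alpha = ln 2 / alpha;
#' T1/2beta = ln 2 / beta; AUC(0-inf) = D/CL = A/alpha + B/beta;
#' MRT = Vss/CL.
#'
#' @param p A `micro_params` object.
#' @param d A `dose_regimen`.
#' @return A list of class `derived_params` with fields `vss`,
#'   `t_half_alpha`, `t_half_beta`, `auc_inf`, `mrt`, `cl`.
#' @export
derived_params <- function(p, d) {
  stopifnot(inherits(p, "micro_params"), inherits(d, "dose_regimen"))
  cl <- p$k10 * p$vc
  vss <- p$vc * (1 + p$k12 / p$k21)
  m <- macro_from_micro(p, d)
  structure(
    list(vss = vss,
         t_half_alpha = log(2) / m$alpha,
         t_half_beta = log(2) / m$beta,
         auc_inf = d$dose_per_kg / cl,
         mrt = vss / cl,
         cl = cl),
    class = "derived_params"
  )
}
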