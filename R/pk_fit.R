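# Per-animal compartmental fitting: curve-stripping initialization,
# weighted nonlinear least squares on log-transformed parameters
# (Levenberg-Marquardt via minpack.lm), and WinNonlin-convention AIC/SBC
# model selection.
#
# Conventions deliberately mirror WinNonlin, the de-facto standard in
# veterinary PK reporting: AIC = n ln(WRSS) + 2p, SBC = n ln(WRSS) + p ln(n).
# Other software adds data-independent constants; the difference never
# changes a model ranking but does change the printed numbers.

WEIGHTING_SCHEMES <- c("uniform", "inverse_y", "inverse_y_squared")

fit_weights <- function(conc, kind) {
  kind <- match.arg(kind, WEIGHTING_SCHEMES)
  switch(kind,
         uniform = rep(1, length(conc)),
         inverse_y = 1 / conc,
         inverse_y_squared = 1 / conc^2)
}

# Quantifiable observations for an IV-bolus fit: BLOQ samples and the
# pre-dose sample at the administration time are excluded.
quantifiable_points <- function(profile, d) {
  keep <- !profile$bloq &
    profile$concentrations > 0 &
    profile$times > d$admin_time
  list(times = profile$times[keep], conc = profile$concentrations[keep])
}

#' Initial bi-exponential estimates by curve stripping
#'
#' Method of residuals: a log-linear regression on the last `n_terminal`
#' quantifiable points yields the elimination phase (B, beta); the
#' residuals of the earlier points above that line, regressed the same
#' way, yield the distribution phase (A, alpha). If no positive residuals
#' remain (effectively mono-exponential data) the distribution phase is
#' set from the C(0) surplus with a near-zero coefficient.
#'
#' @param profile A `concentration_profile`.
#' @param n_terminal Number of terminal points for the elimination phase
#'   (>= 3 and fewer than the quantifiable total).
#' @param d Dose regimen (used only to exclude the pre-dose sample).
#' @return A `macro_params` object with alpha > beta.
#' @export
strip_curve <- function(profile, n_terminal = 4, d = dose_regimen()) {
  stopifnot(inherits(profile, "concentration_profile"))
  pts <- quantifiable_points(profile, d)
  n <- length(pts$times)
  if (n < 5L) {
    abort_insufficient_data(sprintf(
      "curve stripping needs >= 5 quantifiable points, got %d", n))
  }
  if (n_terminal < 3L || n_terminal >= n) {
    abort_invalid_parameter("`n_terminal` must be >= 3 and < number of points")
  }
  if (all(diff(pts$conc) >= 0)) {
    abort_stripping_failure("profile is non-decreasing; cannot strip an IV-bolus decay")
  }

  idx_term <- seq.int(n - n_terminal + 1L, n)
  ft <- stats::lm(log(conc) ~ times,
                  data = list(times = pts$times[idx_term], conc = pts$conc[idx_term]))
  beta <- -unname(stats::coef(ft)[2L])
  if (!is.finite(beta) || beta <= 0) {
    abort_stripping_failure("terminal phase has a non-negative slope")
  }
  coef_b <- exp(unname(stats::coef(ft)[1L]))

  idx_early <- seq_len(n - n_terminal)
  resid <- pts$conc[idx_early] - coef_b * exp(-beta * pts$times[idx_early])
  pos <- resid > 0
  if (sum(pos) >= 2L) {
    fa <- stats::lm(log(r) ~ t,
                    data = list(t = pts$times[idx_early][pos], r = resid[pos]))
    alpha <- -unname(stats::coef(fa)[2L])
    coef_a <- exp(unname(stats::coef(fa)[1L]))
    if (is.finite(alpha) && alpha > beta && is.finite(coef_a)) {
      return(macro_params(coef_a = coef_a, coef_b = coef_b,
                          alpha = alpha, beta = beta))
    }
  }
  # beta-phase-only fallback: distribution coefficient from the C(0) surplus
  surplus <- pts$conc[1L] - coef_b
  coef_a <- max(surplus, coef_b * 1e-6)
  macro_params(coef_a = coef_a, coef_b = coef_b,
               alpha = 10 * beta, beta = beta)
}

#' Fit a one- or two-compartment IV-bolus model to one animal
#'
#' Minimises the weighted residual sum of squares
#' sum w_i (C_i - Chat_i)^2 by Levenberg-Marquardt least squares with
#' parameters log-transformed to enforce positivity. BLOQ samples and the
#' pre-dose sample are excluded before fitting. Deterministic given
#' identical inputs, and invariant to the ordering of the input points.
#'
#' @param profile A `concentration_profile`.
#' @param d A `dose_regimen`.
#' @param n_compartments 1 or 2.
#' @param weighting One of `"uniform"` (default), `"inverse_y"`,
#'   `"inverse_y_squared"`.
#' @param init Optional `macro_params` initial estimate (two-compartment
#'   fits); defaults to [strip_curve()] with `n_terminal = 4`.
#' @param max_iter Maximum optimizer iterations.
#' @param tol Relative convergence tolerance on the objective and
#'   parameters.
#' @return An object of class `pk_fit` with elements `params`
#'   (`micro_params` or `one_comp_params`), `model`, `n_obs`, `n_params`,
#'   `wrss`, `aic`, `sbc`, `converged`, `degenerate` (perfect-fit flag),
#'   `n_iter`, `weighting`, `subject_id`, `dose`.
#' @export
fit_compartmental <- function(profile, d = dose_regimen(),
                              n_compartments = 2,
                              weighting = "uniform",
                              init = NULL,
                              max_iter = 500, tol = 1e-10) {
  stopifnot(inherits(profile, "concentration_profile"), inherits(d, "dose_regimen"))
  if (!n_compartments %in% c(1, 2)) {
    abort_invalid_parameter("`n_compartments` must be 1 or 2")
  }
  weighting <- match.arg(weighting, WEIGHTING_SCHEMES)
  pts <- quantifiable_points(profile, d)
  n_params <- if (n_compartments == 2) 4L else 2L
  if (length(pts$times) == 0L) {
    abort_insufficient_data("no quantifiable observations (all BLOQ or pre-dose)")
  }
  if (length(pts$times) < n_params + 1L) {
    abort_insufficient_data(sprintf(
      "%d-compartment fit needs >= %d quantifiable points, got %d",
      n_compartments, n_params + 1L, length(pts$times)))
  }
  ord <- order(pts$times)
  times <- pts$times[ord]
  conc <- pts$conc[ord]
  w <- fit_weights(conc, weighting)
  sw <- sqrt(w)

  if (n_compartments == 2) {
    start <- two_comp_start(profile, d, init, times, conc)
    pred_fun <- function(theta) {
      p <- exp(theta)
      pm <- list(vc = p[1L], k10 = p[2L], k12 = p[3L], k21 = p[4L])
      class(pm) <- c("micro_params", "pk_params")
      predict_conc_values(pm, d, times)
    }
  } else {
    start <- one_comp_start(d, times, conc)
    pred_fun <- function(theta) {
      p <- exp(theta)
      (d$dose_per_kg / p[1L]) * exp(-p[2L] * times)
    }
  }

  # wild trial steps can overflow exp(theta); return a large flat residual
  # so Levenberg-Marquardt rejects the step instead of crashing
  resid_fun <- function(theta) {
    pred <- tryCatch(pred_fun(theta), error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(rep(1e10, length(conc)))
    sw * (conc - pred)
  }
  fit <- minpack.lm::nls.lm(
    par = log(start), fn = resid_fun,
    control = minpack.lm::nls.lm.control(
      maxiter = min(max_iter, 1024L), ftol = tol, ptol = tol, gtol = 0))

  est <- exp(fit$par)
  params <- if (n_compartments == 2) {
    micro_params(vc = est[1L], k10 = est[2L], k12 = est[3L], k21 = est[4L])
  } else {
    one_comp_params(v = est[1L], k = est[2L])
  }
  wrss <- sum(w * (conc - pred_fun(fit$par))^2)
  n_obs <- length(times)
  structure(
    list(params = params,
         model = if (n_compartments == 2) "two_compartment" else "one_compartment",
         n_obs = n_obs, n_params = n_params,
         wrss = wrss,
         aic = wn_aic(n_obs, wrss, n_params),
         sbc = wn_sbc(n_obs, wrss, n_params),
         converged = fit$info %in% 1:3,
         degenerate = wrss == 0,
         n_iter = fit$niter,
         weighting = weighting,
         subject_id = profile$subject_id,
         dose = d),
    class = "pk_fit"
  )
}

two_comp_start <- function(profile, d, init, times, conc) {
  if (is.null(init)) {
    init <- tryCatch(strip_curve(profile, n_terminal = 4, d = d),
                     calfpkpd_error = function(e) NULL)
  }
  start_micro <- if (!is.null(init)) {
    tryCatch(micro_from_macro(init, d), calfpkpd_error = function(e) NULL)
  }
  if (is.null(start_micro)) {
    # crude fallback: terminal slope for all rates, extrapolated C(0) for Vc
    k_guess <- max(-stats::coef(stats::lm(log(conc) ~ times))[[2L]], 1e-4)
    start_micro <- micro_params(vc = d$dose_per_kg / max(conc),
                                k10 = k_guess, k12 = k_guess, k21 = 2 * k_guess)
  }
  c(start_micro$vc, start_micro$k10, start_micro$k12, start_micro$k21)
}

one_comp_start <- function(d, times, conc) {
  cf <- stats::coef(stats::lm(log(conc) ~ times))
  k <- max(-cf[[2L]], 1e-4)
  v <- d$dose_per_kg / exp(cf[[1L]])
  c(max(v, 1e-6), k)
}

#' WinNonlin-convention Akaike and Schwarz criteria
#'
#' AIC = n ln(WRSS) + 2p and SBC = n ln(WRSS) + p ln(n). A perfect fit
#' (WRSS = 0) returns `-Inf` so the degenerate model is always preferred.
#'
#' @param n Number of fitted observations.
#' @param wrss Weighted residual sum of squares (>= 0).
#' @param n_params Number of estimated parameters.
#' @return A single number (possibly `-Inf` for `wrss == 0`).
#' @export
wn_aic <- function(n, wrss, n_params) {
  if (wrss < 0) abort_invalid_parameter("`wrss` must be >= 0")
  if (wrss == 0) return(-Inf)
  n * log(wrss) + 2 * n_params
}

#' @rdname wn_aic
#' @export
wn_sbc <- function(n, wrss, n_params) {
  if (wrss < 0) abort_invalid_parameter("`wrss` must be >= 0")
  if (wrss == 0) return(-Inf)
  n * log(wrss) + n_params * log(n)
}

#' Select the preferred model order among candidate fits
#'
#' Returns the converged fit with the lowest AIC; ties are broken by
#' fewer parameters, then by lower SBC.
#'
#' @param fits A list of `pk_fit` objects.
#' @return The chosen `pk_fit`.
#' @export
select_model <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "pk_fit")))
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) abort_selection_error("no converged fits to select from")
  fits <- fits[ok]
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  ps <- vapply(fits, `[[`, numeric(1), "n_params")
  sbcs <- vapply(fits, `[[`, numeric(1), "sbc")
  fits[[order(aics, ps, sbcs)[1L]]]
}

TABLE1_PARAMETERS <- data.frame(
  parameter = c("Vc", "V2", "Vss", "CL", "CLD2", "T_half_alpha",
                "T_half_beta", "AUC", "MRT", "K10", "K12", "K21"),
  units = c("mL/kg", "mL/kg", "mL/kg", "mL/h/kg", "mL/h/kg", "h",
            "h", "h*ug/mL", "h", "1/h", "1/h", "1/h"),
  stringsAsFactors = FALSE
)

# all 12 reported parameters for one fitted animal
animal_parameter_row <- function(fit) {
  p <- fit$params
  d <- fit$dose
  cp <- clearance_from_micro(p)
  dv <- derived_params(p, d)
  c(Vc = p$vc, V2 = cp$v2, Vss = dv$vss, CL = cp$cl, CLD2 = cp$cld2,
    T_half_alpha = dv$t_half_alpha, T_half_beta = dv$t_half_beta,
    AUC = dv$auc_inf, MRT = dv$mrt, K10 = p$k10, K12 = p$k12, K21 = p$k21)
}

#' Population summary of per-animal two-compartment fits
#'
#' Computes each animal's primary and derived parameters, then the
#' arithmetic mean and standard error (SD / sqrt(n)) across animals for
#' each of the twelve reported parameters.
#'
#' @param fits A list of converged two-compartment `pk_fit` objects
#'   (all the same model order; n >= 2).
#' @return A data.frame with columns `parameter`, `units`, `mean`, `se`,
#'   of class `population_summary`.
#' @export
summarize_population <- function(fits) {
  stopifnot(is.list(fits), all(vapply(fits, inherits, logical(1), "pk_fit")))
  if (length(fits) < 2L) abort_insufficient_data("population summary needs >= 2 animals")
  models <- vapply(fits, `[[`, character(1), "model")
  if (length(unique(models)) != 1L) {
    abort_invalid_parameter("all fits must share the same model order")
  }
  if (models[1L] != "two_compartment") {
    abort_invalid_parameter("population summary is defined for two-compartment fits")
  }
  mat <- t(vapply(fits, animal_parameter_row, numeric(12L)))
  out <- TABLE1_PARAMETERS
  out$mean <- colMeans(mat)
  out$se <- apply(mat, 2L, stats::sd) / sqrt(nrow(mat))
  rownames(out) <- NULL
  class(out) <- c("population_summary", "data.frame")
  out
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("<pk_fit> %s, %s, n=%d, WRSS=%.4g, AIC=%.4g, SBC=%.4g, converged=%s\n",
              x$subject_id, x$model, x$n_obs, x$wrss, x$aic, x$sbc, x$converged))
  invisible(x)
}
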