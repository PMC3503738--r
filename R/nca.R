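# Non-compartmental analysis: Cmax/Tmax, linear-trapezoid AUC/AUEC over
# an observed window, and the two-group tests applied to those summaries
# (one-way ANOVA for normally distributed single measurements,
# Kruskal-Wallis for Tmax).

#' Peak concentration and time of peak
#'
#' @param profile A `concentration_profile` with at least one observation.
#' @return A list with `cmax` (maximum observed value) and `tmax`
#'   (earliest time attaining it; ties broken by earliest time).
#' @export
cmax_tmax <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (length(profile$times) == 0L) {
    abort_insufficient_data("empty profile has no Cmax/Tmax")
  }
  i <- which.max(profile$concentrations)  # first maximum = earliest tie
  list(cmax = profile$concentrations[i], tmax = profile$times[i])
}

#' Area under the curve by the linear trapezoidal rule
#'
#' Sums 0.5 (C_i + C_(i+1)) (t_(i+1) - t_i) over adjacent observed pairs
#' inside `[t_start, t_end]`. Both bounds must coincide with sampled
#' times: no extrapolation or interpolation is performed.
#'
#' @param profile A `concentration_profile`.
#' @param t_start,t_end Integration bounds (same time units as the
#'   profile); must be sampled times with `t_start < t_end`.
#' @return The area, in time x analyte units.
#' @export
auc_linear_trapezoid <- function(profile, t_start = min(profile$times),
                                 t_end = max(profile$times)) {
  stopifnot(inherits(profile, "concentration_profile"))
  if (t_start >= t_end) abort_invalid_parameter("`t_start` must be < `t_end`")
  tol <- 1e-9 * max(1, abs(t_end))
  i0 <- which(abs(profile$times - t_start) <= tol)
  i1 <- which(abs(profile$times - t_end) <= tol)
  if (length(i0) != 1L || length(i1) != 1L) {
    abort_invalid_parameter(
      "integration bounds must coincide with sampled times (no extrapolation)")
  }
  idx <- seq.int(i0, i1)
  tt <- profile$times[idx]
  cc <- profile$concentrations[idx]
  sum(0.5 * (cc[-1L] + cc[-length(cc)]) * diff(tt))
}

group_test_result <- function(statistic, p_value, test_name) {
  structure(list(statistic = statistic, p_value = p_value, test_name = test_name),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g\n", x$test_name, x$statistic, x$p_value))
  invisible(x)
}

#' Two-group one-way analysis of variance
#'
#' For two groups the F statistic equals the square of the pooled
#' two-sample t statistic, with p from F(1, n - 2). Degenerate inputs
#' (zero variance in both groups) return F = 0, p = 1 when the means
#' agree and F = Inf, p = 0 when they differ.
#'
#' @param a,b Numeric vectors, each with n >= 2.
#' @return A `group_test_result`.
#' @export
compare_groups_anova <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort_insufficient_data("ANOVA needs >= 2 values per group")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(group_test_result(0, 1, "one-way ANOVA"))
    return(group_test_result(Inf, 0, "one-way ANOVA"))
  }
  y <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  tab <- stats::anova(stats::lm(y ~ g))
  group_test_result(tab[["F value"]][1L], tab[["Pr(>F)"]][1L], "one-way ANOVA")
}

#' Two-group Kruskal-Wallis rank test
#'
#' Mid-rank ties with the usual tie correction; p from chi-square(1).
#' If every value is identical the statistic is 0 and p = 1.
#'
#' @param a,b Numeric vectors (each n >= 1, combined n >= 3).
#' @return A `group_test_result`.
#' @export
compare_groups_kruskal <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L || length(a) + length(b) < 3L) {
    abort_insufficient_data("Kruskal-Wallis needs n >= 1 per group, combined n >= 3")
  }
  y <- c(a, b)
  if (length(unique(y)) == 1L) {
    return(group_test_result(0, 1, "Kruskal-Wallis"))
  }
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  kt <- stats::kruskal.test(y, g)
  group_test_result(unname(kt$statistic), kt$p.value, "Kruskal-Wallis")
}

#' Table-style NCA summary for two treatment groups
#'
#' Computes Cmax, Tmax and AUEC per animal over the given window, then
#' group means with standard errors and the between-group p value
#' (ANOVA for Cmax and AUEC, Kruskal-Wallis for Tmax).
#'
#' @param profiles List of `concentration_profile` objects, one per animal.
#' @param treatments Character vector of group labels parallel to
#'   `profiles` (exactly two distinct labels).
#' @param t_start,t_end AUEC integration window (must be sampled times).
#' @return A data.frame with one row per parameter and columns for each
#'   group's mean and SE plus `p_value`.
#' @export
nca_group_table <- function(profiles, treatments,
                            t_start = NULL, t_end = NULL) {
  stopifnot(length(profiles) == length(treatments))
  groups <- unique(treatments)
  if (length(groups) != 2L) abort_invalid_parameter("exactly two treatment groups required")
  per <- lapply(profiles, function(pr) {
    pk <- cmax_tmax(pr)
    ts <- if (is.null(t_start)) min(pr$times) else t_start
    te <- if (is.null(t_end)) max(pr$times) else t_end
    c(cmax = pk$cmax, tmax = pk$tmax,
      auec = auc_linear_trapezoid(pr, ts, te))
  })
  mat <- do.call(rbind, per)
  mkrow <- function(param, test) {
    va <- mat[treatments == groups[1L], param]
    vb <- mat[treatments == groups[2L], param]
    p <- if (test == "anova") compare_groups_anova(va, vb)$p_value
         else compare_groups_kruskal(va, vb)$p_value
    data.frame(parameter = param,
               mean_1 = mean(va), se_1 = stats::sd(va) / sqrt(length(va)),
               mean_2 = mean(vb), se_2 = stats::sd(vb) / sqrt(length(vb)),
               p_value = p, stringsAsFactors = FALSE)
  }
  out <- rbind(mkrow("tmax", "kruskal"), mkrow("cmax", "anova"), mkrow("auec", "anova"))
  names(out)[2:5] <- c(paste0(groups[1L], c("_mean", "_se")),
                       paste0(groups[2L], c("_mean", "_se")))
  out
}
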