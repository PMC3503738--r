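---
title: "Methods: compartmental PK and pain-endpoint statistics in dehorned calves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartmental PK and pain-endpoint statistics in dehorned calves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calfpkpd)
```

# The study design this package models

`calfpkpd` implements the analysis pipeline for a single-dose analgesia
trial in weaned dairy calves: twelve animals, block-randomized in
weight-matched pairs, receive either 0.5 mg/kg meloxicam or saline as an
IV bolus immediately before scoop dehorning. Blood is drawn at 0 (pre-dose),
5, 10, 15, 20, 30 and 60 minutes and at 6, 22, 30, 45 and 52 hours for
meloxicam, cortisol and substance P; heart rate is telemetered at 15-second
intervals; accelerometers classify every 5-second epoch as lying, standing
or walking for 48 h before and 168 h after dehorning; and each calf is
weighed on arrival, just before dehorning and 10 days after.

No raw data accompany the study, so the package ships a fully seeded
synthetic-cohort generator whose defaults are the published design and
effect sizes. Every analysis stage can therefore be exercised, and its
estimators validated, with no external inputs.

# The pharmacokinetic model

## Parameterizations

After an IV bolus dose $D$ (µg/kg), the two-compartment model predicts the
plasma concentration

$$C(t) = A e^{-\alpha t} + B e^{-\beta t}, \qquad A + B = D / V_c,$$

where the hybrid constants relate to the micro-rate constants by the Vieta
identities $\alpha + \beta = k_{10} + k_{12} + k_{21}$ and
$\alpha\beta = k_{10} k_{21}$, with
$A = (D/V_c)(\alpha - k_{21})/(\alpha - \beta)$ and
$B = (D/V_c)(k_{21} - \beta)/(\alpha - \beta)$.

Three equivalent parameter families are supported, because PK reports print
all of them:

* **micro**: $V_c, k_{10}, k_{12}, k_{21}$ — the canonical internal form;
* **clearance**: $V_c, CL, CLD_2, V_2$ with $CL = k_{10} V_c$,
  $CLD_2 = k_{12} V_c = k_{21} V_2$;
* **macro**: $A, B, \alpha, \beta$.

The micro family is the single source of truth; the other two are views,
so conversions can never drift apart. Derived quantities follow the standard
identities: $V_{ss} = V_c (1 + k_{12}/k_{21}) = V_c + V_2$,
$T_{1/2,\alpha} = \ln 2/\alpha$, $T_{1/2,\beta} = \ln 2/\beta$,
$AUC_{0-\infty} = D/CL = A/\alpha + B/\beta$, $MRT = V_{ss}/CL$.

Units are fixed throughout: hours, µg/mL, mL/kg, and dose in µg/kg
(0.5 mg/kg enters once, as 500 µg/kg). A one-compartment model
$C(t) = (D/V)e^{-kt}$ is carried as the competing candidate for model-order
selection.

One caveat worth stating: published population tables average each
parameter across animals *independently*, so a printed mean set need not
satisfy the algebraic identities exactly (mean $k_{10}$ need not equal mean
$CL$ / mean $V_c$). The package therefore treats each parameter family as a
self-consistent set and never mixes families when reconstructing a curve.
Equal roots ($\alpha = \beta$) cannot arise from positive distinct rate
constants within floating tolerance, so the conversion raises an internal
error rather than switching to a $t e^{-\alpha t}$ limiting form.

## Fitting

Per-animal fitting minimises the weighted residual sum of squares
$\sum_i w_i (C_i - \hat C_i)^2$ by Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with all parameters log-transformed, which enforces
positivity and automatically keeps $\alpha > \beta$. Initial estimates come
from curve stripping (method of residuals): a log-linear regression on the
last `n_terminal = 4` quantifiable points gives $(B, \beta)$; the positive
residuals of the earlier points above that line, regressed the same way,
give $(A, \alpha)$. When no usable positive residuals remain — effectively
mono-exponential data — the fallback sets $A$ from the $C(0)$ surplus
(near zero) so the optimizer starts from the elimination phase alone.

Numerical settings: maximum 500 iterations, relative objective/parameter
tolerance $10^{-10}$. These guarantee the recovery contract the tests
enforce — on noise-free data at the study schedule the fit reproduces the
generating parameters to well within 0.1% — while noisy fits that reach the
iteration cap are returned honestly with `converged = FALSE`, never
silently. Non-finite trial steps (an overflowing $e^\theta$ during a wild
Levenberg–Marquardt excursion) are rejected by returning a large flat
residual rather than crashing.

Three weighting schemes are available: `uniform` (default), `inverse_y`
and `inverse_y_squared`. The original software's weighting is not
reported, so the default was chosen for the recovery contract, not for
replication; on noise-free data all three have the same exact minimizer,
which the tests check.

Samples below the 0.025 µg/mL limit of quantification are excluded before
fitting, as is the pre-dose sample at $t = 0$ (drawn before the bolus, it
carries no drug). Exclusions are recorded in the pipeline run log.

## Model selection

Model order (one vs two compartments) is chosen by the
software-convention criteria

$$\mathrm{AIC} = n \ln(\mathrm{WRSS}) + 2p, \qquad
  \mathrm{SBC} = n \ln(\mathrm{WRSS}) + p \ln n,$$

documented prominently because other conventions add data-independent
constants that change the printed values (never the ranking). A perfect
fit (WRSS = 0) maps to $-\infty$ and is always preferred. Selection takes
the lowest-AIC converged fit; AIC ties break by fewer parameters, then by
lower SBC. The population summary computes each animal's twelve reported
parameters (primary plus derived) first, then the arithmetic mean and
standard error (SD/$\sqrt{n}$) across animals per parameter.

# Non-compartmental analysis

Cortisol response is summarized without a model: `cmax_tmax` takes the
observed maximum (ties broken by the earliest time, which is conventional
and deterministic), and `auc_linear_trapezoid` applies the linear
trapezoidal rule between sampled times, with no extrapolation — both
integration bounds must be sampled times, and the AUEC window is a
required analysis parameter because the summary-table window is not
uniquely determined by the design. AUEC is computed on raw concentrations
with no baseline subtraction; the magnitudes of the published summaries are
consistent with raw-scale trapezoids. No log-trapezoid variant is offered:
the linear rule is the named method.

Between-group tests mirror the published choices: one-way ANOVA for
normally distributed single measurements (ADG, Cmax, AUEC), whose
two-group F statistic equals the squared pooled t statistic, and the
Kruskal–Wallis rank test for Tmax. Degenerate inputs follow explicit
conventions (both groups constant and equal means → $F = 0$, $p = 1$;
constant but different → $F = \infty$, $p = 0$; all ranks tied → $H = 0$,
$p = 1$).

# Endpoint statistics

**Substance P.** Values are log-normally distributed, so the treatment
contrast is a geometric-mean ratio: $\exp(\overline{\ln a} -
\overline{\ln b})$ with a pooled-variance t interval back-transformed from
the log scale (natural logs). The exposure–response screen regresses
$\log_{10}$ of the percent change from baseline on $\log_{10}$ of the
same-animal, same-timepoint meloxicam concentration. Base 10 matches the
magnitude of the published regression equation; both bases are stated in
the output headers. Only pairs with a quantifiable concentration and a
*positive* percent change can enter (the logarithm is undefined
otherwise); how the original analysis handled nonpositive changes is not
stated, so excluded pairs are counted in the run log rather than silently
dropped. Only treated animals contribute, since controls have no
quantifiable drug.

**Behavior.** Hourly epoch counts (≤ 720 five-second epochs per hour) are
pooled into pre- (48 h) and post-dehorning (168 h) lying proportions —
a weighted average of hourly proportions with epoch-count weights. Hours
with known human intervention are excluded identically in both arms via a
configuration list. The within-group pre-vs-post change is tested with a
two-proportion z test on the aggregated counts, and the between-group
effect is the difference-in-differences on the proportion scale. This is a
deliberate simplification of the original random-effects logistic
regression: it ignores between-calf correlation, so its p values are
anti-conservative relative to a mixed model, and it is documented as a
fidelity limitation rather than an equivalence claim. A proportion change
is also expressed as standing minutes per day,
$(p_{pre} - p_{post}) \times 1440$.

**ADG.** Average daily gain is pure weigh-in arithmetic — (pre −
arrival)/days and (post − pre)/days — with the group comparison by the
same two-group ANOVA.

**Heart rate.** Per-calf window means first (missing telemetry samples
skipped; a calf with an empty window is excluded with a warning), then
group mean ± SE. The original mixed models for the repeated-measures
endpoints are likewise out of scope.

# The synthetic cohort generator

The generator's defaults *are* the study conditions: 6 calves per arm,
arrival weights uniform on 140–205 kg, pairwise block randomization
(within each ascending-weight pair, the calf drawing the higher uniform
number gets meloxicam), the 12-point sampling schedule, and the published
population mean PK parameters with the 0.025 µg/mL LOQ.

Where the study reports only means ± SE, variability parameters were set
once to values a pharmacometrician would call realistic and consistent
with the published standard errors (SE·$\sqrt 6$):

* PK between-subject variability: lognormal, CV 20%, drawn independently
  per clearance-family parameter (true between-animal correlations are
  unknowable from a summary table, so independence is the documented
  choice); proportional residual error CV 15%.
* Cortisol: baseline 45 nmol/L rising to a 160 nmol/L pulse at 15 min —
  a log-time Gaussian bump, one smooth unimodal shape among many that
  meet the 10–30 min peak-window constraint (the shape is configuration,
  not science) — identical in both arms, with 15% animal-level and
  15% sample-level lognormal noise.
* Substance P: lognormal with control geometric mean 114.7 pg/mL,
  treated:control ratio 0.5, no time trend; animal-level CV 45%
  (matching the published SEM of ≈21 pg/mL at n = 6), sample CV 15%.
* Heart rate: 91 bpm baseline, elevated to 103 bpm for 6 h post-dehorning
  in both arms, a 6 bpm treated-arm dip at hours 8 and 10, animal-level
  SD 9 bpm, residual SD 6 bpm, 5% missingness.
* Behavior: lying probability 0.461 → 0.427 (control) and 0.431 → 0.430
  (treated); binomial counts over 720 epochs/hour; 5% of non-lying
  epochs walking; a configurable human-intervention hour list excluded
  from both arms; optionally one treated calf's record dropped to emulate
  the study's accelerometer failure (on by default).
* Weights: pre-study ADG 0.9 ± 0.3 kg/day over 19 days; post-dehorning
  ADG 1.05 ± 0.32 (treated) vs 0.40 ± 0.61 (control) kg/day over 10 days.

Reproducibility: every endpoint × animal combination draws from its own
RNG substream derived deterministically from the master seed, so
generating a subset of endpoints, or adding new ones, never perturbs
existing draws; the tests verify bit-identical reproduction.

What the generator does *not* emulate — circadian activity rhythms,
HPA-axis dynamics beyond a single pulse, correlated PK parameters,
assay-specific error structure — bounds what passing tests demonstrate:
they validate the estimators against the generator's idealized data, not
the instruments' quirks on real calves.

# Validation strategy and problem sizes

The test suite works at three levels, with problem sizes chosen to keep a
full run under a minute on one CPU:

1. **Exact oracles**: hand-computed conversions, closed-form AUC
   integrals, brute-force polynomial roots, rank-formula enumeration,
   pooled-t closed forms.
2. **Noise-free inversion**: every generator inverts exactly through its
   analysis stage (PK fit to < 0.1%, ADG and proportions exactly).
3. **Monte-Carlo recovery**: 200 seeded replicate cohorts confirm the
   pipeline recovers the configured effect sizes (SP log-ratio, four
   lying proportions, two ADG means) within three Monte-Carlo standard
   errors, and that fitted clearance keeps a median absolute relative
   error below 10% at 15% assay noise (200 replicates × 6 animals).

# Known limitations

* The simplified behavior and repeated-measures contrasts are not the
  original mixed models; their p values are comparable in spirit, not in
  distribution.
* Exact reproduction of the published per-animal parameter table is
  impossible in principle (the raw data were never deposited and the
  original fitting software's weighting is unreported); the package's
  contract is parameter *recovery*, which is testable.
* No extravascular absorption, multi-dose superposition, or nonlinear
  elimination; the model scope is a single IV bolus.
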