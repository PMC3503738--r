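# calfpkpd

Pharmacokinetic and pain-endpoint analysis for a single-dose meloxicam
dehorning trial in weaned dairy calves.

Dehorning is routine on dairy operations and is rarely accompanied by
analgesia. A practical question for veterinarians is whether one IV bolus
of a long-lived NSAID (meloxicam, 0.5 mg/kg), given immediately before
dehorning without a local nerve block, changes the physiological and
behavioral signs of pain and the animals' subsequent performance. Answering
it takes a full small-trial pipeline — plasma drug kinetics, stress
biomarkers, telemetry, accelerometry, weigh-ins — and this package
implements that pipeline as tested, reusable R code, together with a seeded
synthetic-cohort generator that reproduces the study design (no raw trial
data were ever deposited).

## What it computes

**Compartmental PK.** The two-compartment IV-bolus model
C(t) = A·e^(−αt) + B·e^(−βt), with the three standard parameter families
(micro-rate constants k10/k12/k21, clearances CL/CLD2, macro constants
A/B/α/β) interconvertible and the derived set Vss, T½α, T½β, AUC₀₋∞, MRT.
Per-animal fits use curve stripping for initial estimates, then
Levenberg–Marquardt weighted nonlinear least squares on log-transformed
parameters; model order (1 vs 2 compartments) is selected by
AIC = n·ln(WRSS) + 2p and SBC = n·ln(WRSS) + p·ln(n); the population table
reports mean ± SE of all twelve parameters across animals.

**NCA.** Cmax, Tmax (earliest-time ties) and linear-trapezoid AUC/AUEC over
an observed window, with two-group ANOVA (Cmax, AUEC, ADG) and
Kruskal–Wallis (Tmax) tests.

**Endpoints.** Substance P geometric-mean treatment ratio with a pooled-t
confidence interval on the log scale; log10–log10 regression of SP percent
change from baseline on same-timepoint meloxicam concentration; lying
behavior pooled from 5-second accelerometer epochs into pre/post
proportions with two-proportion contrasts and a difference-in-differences;
average daily gain from the three weigh-ins; heart-rate pre/post group
means.

**Simulation.** `simulate_cohort()` draws a complete 12-calf study —
weight-matched pair randomization, PK profiles with lognormal
between-animal variability, proportional assay error and 0.025 µg/mL LOQ
censoring, a cortisol pulse, lognormal substance P with a configurable
treatment ratio, heart-rate telemetry, hourly behavior counts (with an
optional accelerometer-failure dropout) and weigh-ins — deterministically
from one seed, with per-endpoint RNG substreams.

## Worked example

```r
library(calfpkpd)

d <- dose_regimen(500)                    # 0.5 mg/kg IV, stored as ug/kg
cohort <- simulate_cohort(study_config()) # full synthetic study

# per-animal fits with AIC/SBC model-order selection
fits <- lapply(Filter(function(p) any(!p$bloq), cohort$pk), function(p) {
  select_model(list(fit_compartmental(p, d, 1), fit_compartmental(p, d, 2)))
})
two_comp <- Filter(function(f) f$model == "two_compartment", fits)
summarize_population(two_comp)
```

```
      parameter   units      mean       se
1            Vc   mL/kg 102.47500 15.99553
2            V2   mL/kg 100.95892 14.81892
3           Vss   mL/kg 203.43392  7.29441
4            CL mL/h/kg   6.68903  0.36793
5          CLD2 mL/h/kg 189.50685 36.94989
6  T_half_alpha       h   0.19734  0.03950
7   T_half_beta       h  21.40664  0.76567
8           AUC h*ug/mL  75.69822  4.31679
9           MRT       h  30.60583  1.13079
10          K10     1/h   0.07186  0.01068
11          K12     1/h   2.29159  0.74136
12          K21     1/h   1.86314  0.18583
```

The simulated cohort is drawn around population means of CL 6.64 mL/h/kg
and Vc 94.88 mL/kg with 20% between-animal CV and 15% assay noise; the
recovered means (CL 6.69 ± 0.37, terminal half-life 21.4 h) land within
sampling error of the generating values — a drug cleared slowly enough
that one pre-surgical bolus stays above reported effective concentrations
for days.

```r
# substance P treatment contrast and behavior/performance endpoints
sp <- cohort$sp
gm  <- tapply(sp$value, sp$subject_id, function(v) exp(mean(log(v))))
trt <- tapply(sp$treatment, sp$subject_id, `[`, 1)
geometric_mean_ratio(gm[trt == "meloxicam"], gm[trt == "control"])
prepost_treatment_contrast(cohort$behavior)$by_group
adg(cohort$weights)
```

```
SP ratio 0.46 (95% CI 0.26-0.81)
  treatment p_pre p_post   p_value minutes_per_day
1   control 0.460  0.428 1.43e-144           46.10
2 meloxicam 0.429  0.431  2.99e-01           -2.05
ADG post: meloxicam 0.96 vs control 0.61 kg/day
```

Treated calves show roughly half the substance P of controls, no change in
lying time where controls stand ~46 more minutes per day after dehorning,
and better weight gain — the configured effect pattern, recovered by the
analysis stages from one noisy 12-calf draw. `run_pipeline(pipeline_config(...))`
chains all stages and writes the population-PK, cortisol-NCA and endpoint
CSVs plus a run log recording the seed and every excluded observation.

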