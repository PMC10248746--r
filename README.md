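# abxgvhd

Estimating associations between time-dependent antibiotic exposures and
acute graft-vs-host disease (aGVHD) after allogeneic hematopoietic cell
transplantation (allo-HCT), with death before aGVHD treated as a competing
risk.

Antibiotic exposure around transplant is a moving target: drugs start and
stop daily, prescribing responds to the same clinical deterioration that
predicts aGVHD, and follow-up is truncated by death. `abxgvhd` is written
for biostatisticians and transplant researchers who need to analyse
person-day antibiotic administration data against a competing-risk
endpoint, and for methodologists who want a tested environment in which all
three standard estimators run against simulated cohorts with known ground
truth.

## What it implements

Exposures between day −7 and day +30 (day 0 = transplant) are coded as one
binary time-dependent covariate per antibiotic class × interval, using a
17-class catalogue and five roughly week-long intervals ([−7,−1], [0,6],
[7,13], [14,20], [21,30]) — 85 exposure columns, 94 model variables with
the nonantibiotic covariate slots. Three estimators share this encoding:

1. **Fine–Gray proportional hazards with time-dependent covariates** — a
   weighted partial-likelihood engine (Newton–Raphson in C++, Efron or
   Breslow ties) on counting-process rows
   `λ₁(t | X(t)) = λ₀(t) · exp(βᵀX(t))`, with competing-event patients
   retained in risk sets at weight `G(t)/G(t_death)` (censoring
   Kaplan–Meier), perfect-separation merging, and AIC-guided backward
   elimination that merges adjacent intervals with similar associations or
   removes classes with none.
2. **Marginal structural model** — pooled per-day logistic treatment
   models for class initiation; stabilized weights
   `sw(t) = Π_{s≤t} p_num(s)/p_den(s)`; weighted competing-risk fit with
   patient-clustered sandwich variance.
3. **Shadow-feature (Boruta) selection** — random-forest out-of-bag
   permutation importance against re-shuffled shadow features,
   binomial hit tests with Bonferroni correction, resumable iterations.

A seeded discrete-time simulator (`simulate_cohort()`) generates
allo-HCT-like cohorts — confounded daily exposure, interval-specific
multiplicative effects on the aGVHD hazard, competing death, engraftment
times, administrative censoring at day 180 — with the ground truth
recorded for parameter-recovery testing.

## Worked example

Simulate a cohort in which carbapenem exposure during week 1 after
transplant carries a true hazard ratio of 2.75, encode it, and fit the
time-dependent competing-risk model:

```r
library(abxgvhd)

cfg <- preset_scenarios()$carbapenem_week1
cfg$n_patients <- 600L
cohort <- simulate_cohort(cfg, seed = 42)
print(cohort)
#> Synthetic cohort: 600 patients, 21946 administration records
#>   aGVHD by day 180: 84.3%; death without aGVHD: 0.0%

design <- encode_exposures(cohort$records, cfg$scheme, cfg$catalogue,
                           patients = cohort$covariates$patient_id)
print(design)
#> Exposure design: 600 patients, 3 classes x 5 intervals -> 15 columns (persistent coding)
#>   4382 patient-column exposures observed; 0 record(s) dropped out of window

expansion <- expand_counting_process(design, cohort$covariates, cohort$outcomes)
expansion <- fine_gray_extend(expansion, cohort$outcomes)
fit <- fit_td_hazard(expansion)
subset(render_hr_table(fit), grepl("carbapenems", term))
#>             term   hr ci_lower ci_upper        p significant
#>  carbapenems__i1 0.98    0.805     1.19 8.40e-01       FALSE
#>  carbapenems__i2 2.97    2.450     3.60 1.59e-28        TRUE
#>  carbapenems__i3 1.01    0.824     1.23 9.39e-01       FALSE
#>  carbapenems__i4 1.04    0.845     1.28 7.07e-01       FALSE
#>  carbapenems__i5 0.92    0.713     1.19 5.21e-01       FALSE
```

Only the week-1 term (`__i2`, days 0–6) is significant, and its estimate
(HR 2.97, CI 2.45–3.60) brackets the simulated truth of 2.75; the other
intervals, simulated with no effect, sit near 1. From here,
`backward_eliminate()` reduces the model by AIC,
`fit_treatment_models()` / `stabilized_weights()` / `fit_msm()` give the
MSM analogue, `run_boruta()` runs feature selection on the patient-level
binary matrix, and `run_pipeline()` chains all three from a single YAML or
list configuration.

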