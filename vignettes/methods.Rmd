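---
title: "Estimating antibiotic-aGVHD associations under competing risks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating antibiotic-aGVHD associations under competing risks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Recipients of allogeneic hematopoietic cell transplantation (allo-HCT)
receive many antibiotics in the weeks around the graft infusion (day 0).
Antibiotic-driven injury to the gut microbiota is a suspected risk factor
for acute graft-vs-host disease (aGVHD), but exposure is time-dependent,
strongly confounded by the clinical events that prompt prescribing, and
follow-up is cut short by death without aGVHD — a competing risk.  No
single estimator handles all of this well, so `abxgvhd` implements three
complementary ones operating on a shared exposure encoding, plus a
synthetic cohort generator with known ground truth to validate them.

# Exposure encoding

Administration records (`patient_id, day, abx_class`) over the window from
7 days before to 30 days after transplant are summarized per antibiotic
class and interval.  The default partition pins one boundary at the day
-1/0 transition so the pre-transplant days form their own interval:
[-7,-1], [0,6], [7,13], [14,20], [21,30] — about one week each, the last
interval absorbing the remainder.  The default catalogue holds 17 classes
(with beta-lactamase-inhibitor and oral/IV splits), giving 85 binary
time-dependent columns; with the nine nonantibiotic covariate slots the
full model carries 94 variables.

Each (class, interval) column switches from 0 to 1 at the first
administration day of that class inside that interval.  Two codings are
available because the exposure literature uses both and the choice is
genuinely open:

* **persistent** (default): the indicator stays 1 for the rest of
  follow-up, so the term measures the hazard associated with *having been
  exposed* in that interval.  All paths are then monotone, which the tests
  assert.
* **transient** (`coding = "transient"`): the indicator is active only
  from first exposure through the interval's end.

We default to persistent coding because interval-specific effects on later
hazard are the scientific target (aGVHD typically onsets weeks after the
exposures of interest), and because it makes merged-interval columns
well-defined (the merged column switches at the earliest constituent
switch day).

# Model 1: time-dependent proportional hazards with competing risks

Follow-up is expanded into counting-process rows broken at every covariate
switch day; a row `[start, stop]` is at risk on that whole run of days and
carries constant covariates.  The engine maximizes the weighted partial
likelihood by damped Newton-Raphson (step-halving, convergence when the
max coefficient update or score max-norm drops below `1e-8`, at most 100
iterations).  Ties — heavy, because event days are integers — use the
Efron approximation by default, Breslow optionally.  The implementation is
validated in the test suite against brute-force grid maximization of an
independently written partial likelihood on small fixtures, and against
the `survival` package on random weighted fixtures (coefficients,
log-likelihoods, model and robust standard errors agree to at least
`1e-4`).

Death without aGVHD is treated as a competing risk in the Fine-Gray
(subdistribution) sense: patients with a competing event remain in risk
sets after death, weighted by the inverse probability of censoring
G(t)/G(t_death), where G is the Kaplan-Meier estimate of the censoring
distribution evaluated left-continuously on the day grid.  Because
covariates do not exist after death, their paths are carried forward from
the competing event (LOCF).  **Known limitation:** with time-dependent
exposures this convention depresses late-interval exposure prevalence in
extended risk sets (dead patients can never switch on), which shifts
late-interval coefficients upward relative to a cause-specific truth even
under a null — a property of the modelling convention, not of the
implementation.  The parameter-recovery presets therefore use a zero
death hazard so the cause-specific truth coincides with the
subdistribution estimand.

Nonantibiotic covariates enter as graft source, conditioning intensity,
ATG use, the donor-type-by-prophylaxis interaction, recipient age, and two
engraftment terms: a non-engraftment indicator plus days-to-engraftment
with non-engrafters assigned the median day among engrafters, so the
indicator compares them to a hypothetical median engrafter.  The covariate
schema is extensible; age fills the ninth slot because the source
literature does not print its full nonantibiotic list.

Degenerate columns (constant over the risk experience) are dropped with a
warning.  A coefficient diverging past 15 in absolute value with a still
monotone likelihood is reported as a separation diagnostic naming the
term.  `compute_vif()` supplies the collinearity check (ordinary
least-squares R-squared of each term on the others over expansion rows).

# Interval selection

Perfect separation (all or none of a column's exposed patients have the
event) is resolved before fitting by merging the flagged column with an
adjacent same-class column — the earlier neighbour first, the later one
when no earlier neighbour exists; a class still separated after collapsing
to a single column is dropped with a warning.  We use this deterministic
adjacency rule rather than an AIC comparison because separation handling
happens before any stable fit exists.

Backward elimination then iterates two candidate moves: merging two
adjacent same-class intervals with *similar associations* — both
significant (2-sided Wald p < 0.05) with the same coefficient sign, or
both non-significant — and removing a class non-significant in all its
intervals.  Every candidate is refitted, the largest strict AIC decrease
wins (ties broken by catalogue order, then chronology; merges evaluated
before removals), and the procedure stops at an AIC fixed point.  The
greedy best-AIC rule is an assumption recorded in the audit trace, which
stores every evaluated candidate with its AIC before/after and acceptance
flag.  Covariate terms are never candidates.  For the severe-grade
endpoint the pipeline can restrict the antibiotic term set to the classes
(or columns) significant in the broader-grade model via
`antibiotic_terms`, mirroring the carried-over-significance workflow.

# Model 2: marginal structural model

Daily treatment decisions are modelled as *first initiation per class per
interval*: while a class's current-interval column is off, each day is a
Bernoulli decision; once on, the indicator is deterministic and
contributes probability 1.  Rather than one logistic model per calendar
day (unfittable at realistic sizes), person-days are pooled with interval
fixed effects — per-day structure enters through those effects, and the
previous-day exposure state enters as one persistent on/off indicator per
class.  The denominator model adds baseline covariates and any measured
time-varying confounders; the numerator conditions on treatment history
and interval effects only, so the baseline terms in the outcome model
absorb the baseline dependence.  The stabilized weight is the cumulative
product over days of the probability ratio of the observed action, carried
forward unchanged after the exposure window.  Fitted probabilities of
exactly 0 or 1 raise a positivity error; optional percentile truncation is
available but off by default.

`fit_msm()` re-breaks the expansion at every day of the exposure window so
the weight is constant within rows, multiplies stabilized IPTW with the
Fine-Gray IPCW, and uses a patient-clustered sandwich variance (score
residuals that sum exactly to the score, including under Efron ties), as
model-based variances are anticonservative under weighting.

Treatment models are fitted over all window person-days, including days
after a patient's event; because the treatment process does not depend on
outcome history, this is consistent and uses the data fully, and weights
applied to risk rows at day t only involve decisions up to t.

**Finite-sample behaviour.** IPTW estimators with variable weights carry
a finite-sample bias that shrinks with cohort size, so in strongly
confounded scenarios the MSM reduces — rather than eliminates —
confounding bias at realistic n.  The automated confounding study
therefore compares *batch-level* absolute bias of the MSM against the
unweighted fit rather than asserting exact unbiasedness.

# Model 3: shadow-feature selection

`run_boruta()` is a from-scratch implementation of the shadow-feature
wrapper: each iteration re-shuffles a shadow copy of every feature, trains
a random forest (`randomForest`, 500 trees by default, `mtry` the square
root of the augmented width) and awards a hit to every original feature
whose out-of-bag permutation importance (unscaled mean decrease accuracy)
beats the best shadow.  After each iteration a two-sided binomial test
(p = 0.5) with Bonferroni correction across still-unresolved features
declares features important or unimportant; decisions freeze once made, so
extending a run can resolve tentatives but never flips a decision.
`extend_boruta()` continues the same RNG stream, making `run(a)` then
`extend(b)` identical to `run(a + b)` — mirroring the add-more-iterations
usage for unresolved features.  Patients dying without aGVHD before day
180 are excluded from the feature matrix (the selector is not
competing-risk aware); censored-before-horizon patients keep outcome 0.

One behaviour worth knowing: on a *given* dataset with a permuted outcome,
features with chance correlations of |r| around 0.1 are sometimes declared
important — correctly, conditionally on that dataset.  Null calibration
checks therefore run at cohort scale (n = 2000), where chance correlations
are negligible.

# The synthetic cohort generator

`simulate_cohort()` is a discrete-time simulation on integer days encoding
exactly the structure the estimators assume: daily class initiation from a
logistic process (intercept -3.2; +0.8 for the same class active the
previous day; +0.3 for any other class; +0.3 for myeloablative
conditioning), a Markov illness ("fever") indicator able to raise both
initiation odds and the aGVHD hazard (the only measured-vs-unmeasured
confounder toggle), a piecewise-constant daily aGVHD hazard multiplied by
exp(log-HR) per active class-interval exposure, an independent constant
death hazard, and administrative censoring at day 180.  Cause-specific
events are drawn per day via 1 - exp(-hazard), aGVHD first.  Baseline
hazards (0.008, 0.022, 0.030, 0.006, 0.0015 per day over days 1-14,
15-28, 29-42, 43-90, 91-180) were calibrated once so the null scenario
gives about 70% grade II-IV incidence by day 180 with median onset near
day 29, matching the reported cohort environment; they are realism
anchors, not fitted quantities.  Engraftment days are
Normal(17, 3) rounded with 2% non-engrafters.  The default catalogue is a
3-class subset (carbapenems, fluoroquinolones, IV vancomycin) so
repeated-fit studies stay cheap; the full 17-class catalogue is available
everywhere.

Presets: `null` (no effects), `confounded_null` (persistent fever, logit
+2 on initiation, log-HR 1.6 on hazard, true exposure HRs 1, no competing
deaths — a deliberately strong measured-confounding demonstration),
`carbapenem_week1` (single true HR 2.75 on carbapenems in week 1, no
deaths), `multi_effect` (several nonzero HRs).  What the generator does
*not* emulate: realistic co-prescription correlation beyond previous-day
dependence, dose/duration effects, informative dropout, or microbiome
dynamics — so passing recovery tests shows estimator correctness under the
assumed data-generating structure, not robustness to violations of it.

# Study sizes used in the automated checks

The acceptance studies run at: 120 replicates of n = 2023 for recovery of
HR 2.75 (mean within 2 Monte-Carlo SEs, CI coverage in [0.91, 0.99]),
fitted with the exposure terms only since the scenario is unconfounded; 30
replicates of n = 2023 in 3 batches for the confounding-correction
comparison; 50 replicates of n = 220 for null-selection pruning (under
half the classes survive on average); shadow-feature checks at n = 400
(positive control) and n = 2000 with 60-100 iterations (null).  These
sizes were chosen to give stable Monte-Carlo summaries on a single CPU;
the same studies scale up unchanged.

# Numerical choices and degenerate inputs

* Convergence: max |coefficient update| or score max-norm below `1e-8`;
  at most 100 Newton iterations with up to 10 step-halvings.
* The linear predictor is centred by its weighted mean before
  exponentiation for overflow safety; results are invariant to the shift.
* Duplicate same-day administrations collapse; records outside the window
  are dropped with a count.
* Interval schemes must cover the window contiguously; infeasible
  partitions (window smaller than the interval count) error.
* All-zero/all-one columns are dropped before fitting, rank deficiency is
  an error naming the terms, and G(t_death) = 0 makes the IPCW weight
  undefined (error).
* Weight-scale invariance (multiplying all case weights by a constant)
  is exact and asserted in the tests.
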