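---
title: "Monitoring kidney function with an age-adjusted CUSUM of eGFR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring kidney function with an age-adjusted CUSUM of eGFR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cusumgfr)
library(dplyr)
```

## The problem

Chronic kidney disease is mostly silent while it is still treatable. A
patient's estimated glomerular filtration rate (eGFR) is recomputed every
time a serum creatinine is drawn, but single values are noisy: eGFR moves
with hydration, medication, assay and age, and the decline path toward
end-stage kidney disease (ESKD) can be linear, nonlinear, or erratic.
Fitting a regression line per patient is fragile on irregularly spaced,
sparse series; what a clinician actually wants to know is *when something
changed*.

`cusumgfr` treats this as a sequential change-detection problem. It
implements a one-sided, zero-capped cumulative-sum (CUSUM) statistic over a
patient's eGFR series, referenced against the distribution of eGFR in
patients with no evidence of kidney disease, with the reference mean
adjusted for healthy aging. When the accumulated standardized shortfall
crosses a tuned threshold the patient *signals* as likely to progress to
ESKD — typically years before the diagnosis.

## The statistic

eGFR is computed from serum creatinine with the 2021 race-free CKD-EPI
creatinine equation (`ckd_epi_2021()`). For a patient's time-ordered
measurements $eGFR_1, eGFR_2, \dots$ the statistic is

$$
C_0 = 0, \qquad
C_i = \min\!\left[\,0,\; \frac{eGFR_i - \hat\mu_i}{\hat\sigma} + w + C_{i-1}\right],
$$

where

* $\hat\mu_i = \hat\mu_0 - d\,\Delta t_i$ is the **age-adjusted reference
  mean**: $\hat\mu_0$ is the Normal-Group mean eGFR at the patient's
  integer age at their *first* measurement, $d$ is the annual decline in
  healthy adults (default $d = 0.81$ mL/min/1.73 m²/yr, the National
  Kidney Foundation figure), and $\Delta t_i$ is elapsed time since the
  first measurement in years (actual/365.25);
* $\hat\sigma$ is a single pooled SD of Normal-Group eGFR around its age
  means;
* $w \ge 0$ is the **allowance**: the per-observation standardized
  shortfall tolerated before anything accumulates. Larger $w$ forgives
  larger benign dips; $w\hat\sigma$ is the "clinically meaningful shift"
  in eGFR units;
* the outer $\min[0,\cdot]$ caps the statistic at zero, so only
  *persistent downward* shifts accumulate and recovery can never build a
  positive reserve.

The patient signals at the first $i$ with $C_i \le T$ for a non-positive
threshold $T$. The boundary is deliberately **inclusive** — a trace that
lands exactly on $T$ signals — and the state is never reset afterwards:
only the first crossing is reported, because one signal date per patient
is what downstream earliness summaries consume. **Earliness** is the
calendar-day difference from signal date to ESKD diagnosis date (positive
when the signal came first).

Two consequences of the recursion are worth knowing and are enforced as
property tests: traces are pointwise monotone in $w$ (growing $w$ can only
raise the trace, hence shrink the signaled set at fixed $T$), and
thresholds are nested (every patient signaling at $T_1 \le T_2$ also
signals at $T_2$, no later).

## Cohort construction

`build_cohort()` applies the selection rules to raw lab/diagnosis tables
and logs every exclusion with a stage and reason, so that
`input = retained + excluded` holds at each stage:

1. **Acute kidney injury**: patients whose record has *every* eGFR below
   90 mL/min/1.73 m² *and* spans at most 92 days are excluded. The
   underlying clinical phrase ("all eGFRs < 90 within 3 months") admits
   several readings; this one removes short acute episodes without
   discarding chronic patients, and the window is configurable.
2. **ESKD Group**: patients with a dated ESKD diagnosis code (ICD-9
   585.6 / ICD-10 N18.6 by default; matching is prefix-wildcard-aware),
   diagnosis date = earliest matching code. Patients whose *first* eGFR is
   below 60 are excluded (boundary inclusive: exactly 60 is retained) —
   they are already identifiable without a monitoring statistic — as are
   patients with fewer than 2 pre-diagnosis observations, for whom no
   trace exists to score.
3. **Normal Group**: non-ESKD patients with no code in a configurable
   CKD exclusion list, no eGFR below 60 anywhere, and at least 9
   observations.

The minimum-observation rule applies to the Normal Group only; it exists
so the reference is estimated from genuinely longitudinal series.
Post-diagnosis observations of ESKD patients are excluded from scoring —
signaling after diagnosis is clinically moot — so a true positive is by
construction a *pre-diagnosis* signal and an ESKD patient who only crosses
after diagnosis counts as a miss.

## The normal reference

`estimate_reference()` computes $\hat\mu_0(a)$ as the mean eGFR over all
Normal-Group measurements taken at each integer age $a$ (floor of
fractional age), with sparse bins (fewer than 10 measurements by default)
falling back to the overall mean, and $\hat\sigma$ as the pooled SD of
residuals around the age means. The residual SD — rather than the marginal
SD of all measurements — is the consistent choice because the statistic
standardizes deviations from the *age-specific* mean; the marginal SD over
a cohort spanning five decades of age would conflate the age trend with
visit-level noise. Integer-age bins rather than interpolation follow how
per-age reference tables are reported in practice; the choice is flagged
for sensitivity analysis, and ages outside the table fall back to the
overall mean.

`reference_normality_check()` tests whether the reference distribution is
adequately described by a (mean, SD) pair, using a one-sample
Kolmogorov–Smirnov test at $\alpha = 0.05$ on the **per-patient mean**
eGFR. Per-visit values are clustered — a patient's visits share that
patient's age-level mean — and pooling them violates the KS test's
independence assumption, making it over-reject even when the marginal
distribution is normal; per-patient means are independent units.
`ks_normality_check()` remains available for arbitrary value vectors.

## Tuning and evaluation

`kfold_tune()` chooses $(w, T)$ by stratified $k$-fold cross-validation
(default $k = 10$, default grids $w \in \{0.25, 0.5, 0.75, 1, 1.25\}$,
$T \in \{-2, \dots, -6\}$, bracketing the clinically useful region): folds
are stratified by group so each test fold contains both classes, per-fold
test sensitivity/specificity/accuracy are averaged per grid point, and the
optimum maximizes mean accuracy with ties broken by Youden's $J$ and then
by the more negative threshold (preferring the more specific rule at equal
headline performance). Because accuracy is a single scalar listed first
among the published metrics, it is the default objective.

Two cross-validation modes exist because it is genuinely open whether the
reference should be fixed while tuning: by default the reference is
re-estimated from each fold's *training* Normal patients, so no patient is
scored against a reference they contributed to (leakage-safe); passing
`refit_reference = FALSE` with a global reference reproduces the simpler
protocol in which the Normal Group both defines the reference and is
scored as negatives. On well-separated data the two agree; on marginal
data the leakage-safe mode is the honest one.

`roc_curve()` sweeps a threshold grid at fixed $w$ — the expensive part of
the computation, the trace, depends on $w$ only, so one pass per $w$
suffices — and reports trapezoid AUC with the curve anchored at $(0,0)$
and $(1,1)$. `earliness_summary()` reports mean (with SD/$\sqrt n$
standard error), median, and the share of true positives signaling while
eGFR was still $\ge$ 30 / 45 / 60. `subgroup_performance()` stratifies by
demographics or comorbidity flags and compares earliness between levels
with a Welch test, flagging levels that lack one of the classes as
undefined rather than erroring.

## The synthetic cohort generator

Real EHR extracts of this kind are not redistributable, so
`simulate_cohort()` generates cohorts with the statistical structure the
method assumes, and every pipeline stage is tested against it:

* **Normal patients**: latent eGFR declines from an age-indexed entry mean
  at $d = 0.81$/yr; the entry-mean schedule is
  $\mu(a) = 85.07 + 0.81\,(64.5 - a)$, i.e. per-age means follow the same
  decline the statistic adjusts for, anchored at mean eGFR 85.07 at the
  reference age 64.5. Visit noise is independent Gaussian with SD 7.8
  (an AR(1) switch exists for robustness experiments), and draws below 60
  are redrawn from the truncated normal, matching the Normal-Group
  definition. Entry ages are Normal(64.5, 10) truncated to [35, 85];
  at least 9 visits are guaranteed.
* **Progressors**: entry ages Normal(57.9, 10); first eGFR conditioned
  $\ge 60$; latent trajectories mix three shapes (40% *rapid*: healthy
  decline until a change point at 1–4 years, then a slope of 10–20
  mL/min/1.73 m²/yr; 40% *slow-linear*: 6–12/yr throughout; 20%
  *nonlinear*: convex exponential decay toward a low asymptote). The
  diagnosis date is the closed-form first crossing of the latent
  trajectory through eGFR 15 (the dialysis-range boundary); trajectories
  that cannot reach it within 12 years are resampled, with a bounded
  retry count so degenerate configurations (zero slopes) fail loudly.
  Observed eGFR is floored at 4 — lower values imply creatinine outside
  the undialysed range.
* **Visit process**: gaps are $1 + \text{NegBin}(\text{mean} \approx 120
  \text{ d}, \text{size } 2)$, giving the wide, irregular spacing seen in
  practice.
* **Demographics and flags**: sex, race and five comorbidity flags are
  sampled per group with prevalences matching a large published
  normal-vs-ESKD comparison (e.g. hypertension 54% vs 89%).
* **Decoys**: optionally, patients violating exactly one selection rule
  each (acute episode, a sub-60 value, too few observations, a CKD code,
  initial eGFR < 60, too few pre-diagnosis observations), so the cohort
  builder's exclusion log can be compared to ground truth exactly.

Everything is emitted as raw creatinine via the analytic inverse of the
CKD-EPI equation, so tests exercise the full creatinine → eGFR → CUSUM
path, and all randomness flows from a single seed.

What the generator does *not* emulate — and therefore what passing tests
cannot show — includes: patient-level random intercepts (every normal
patient sits exactly on the age schedule, so real-data specificity will be
lower than simulated), assay mixtures and unit errors, duplicate records,
informative visit timing (sicker patients being measured more often), and
eGFR improvement under treatment. Simulated groups are separated by
construction (progressor excess decline of at least ~5 mL/min/1.73 m²/yr
over the healthy rate), so near-perfect simulated operating points are a
*recovery* check, not a forecast of performance on clinical data.

## Numerical choices and degenerate inputs

* Elapsed time and ages use an actual/365.25 calendar basis; fractional
  ages avoid step artifacts within long series.
* The CKD-EPI inverse is solved analytically on the branch consistent
  with creatinine above/below the sex knot, so round trips are exact to
  ~1e-12; targets whose implied creatinine falls outside 0.01–100 mg/dL
  raise a domain error, and creatinine above 20 mg/dL is passed through
  the forward map with a warning rather than censored.
* A one-observation series is valid and yields a one-value trace.
* A constant Normal Group (pooled SD 0) is an error, not a silent zero;
  so are confusion metrics with an empty class.
* Truncated-normal draws use the inverse-CDF, so zero-SD and
  near-empty-mass configurations are detected exactly rather than by
  rejection-loop timeout.
* Duplicate or out-of-order measurement dates within a patient are an
  error; observations must be strictly ordered for the recursion to mean
  anything.

## Problem sizes

The test suite validates the recursion against an independently coded
oracle on 1,000 random series (to 1e-12), monotonicity on 500, inversion
round trips on 1,000, cohort ground-truth recovery on a 250-patient cohort
with 18 decoys, and tuning recovery on a 2,000 + 500 patient cohort with
10-fold cross-validation over the default 5×5 grid. The reference-recovery
check uses 2,000 simulated normal patients, and the normality acceptance
rate is measured over 50 seeds of 150 patients each. `scripts/acceptance.R`
re-runs the 2,000 + 500 pipeline from scratch at a caller-supplied seed
and writes the resulting quantities as JSON.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_normal = 300, n_progressor = 75, seed = 2026)
sim <- simulate_cohort(cfg)
cohort <- build_cohort(sim$labs, sim$demographics, sim$diagnoses)
ref <- estimate_reference(cohort_labs(cohort, "normal"))
tuning <- kfold_tune(cohort, k = 10, seed = 2026)
eval <- classify_cohort(cohort, ref, tuning$best$w, tuning$best$threshold)
glance(eval)
earliness_summary(eval)
autoplot(run_cusum(cohort_labs(cohort, "eskd"), ref,
                   tuning$best$w, tuning$best$threshold))
```

## Limitations

The reference is estimated from regular healthcare utilizers (the
nine-measurement rule), who are not a random population sample; a health
system deploying the statistic should re-estimate $\hat\mu_0(a)$ and
$\hat\sigma$ on its own normal population. The statistic is one-sided by
design and says nothing about eGFR improvement. Cross-validated operating
points on synthetic cohorts transfer to real data only to the extent the
generator's assumptions hold, which is exactly what the previous sections
delimit.
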