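---
title: "Validating the Shock Index-C risk score: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating the Shock Index-C risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sicstrat)
```

## The score and the problem

Patients admitted with ST-segment elevation myocardial infarction (STEMI)
and treated with percutaneous coronary intervention face meaningful
in-hospital risk: death (3-4%), acute heart failure, stroke, dialysis,
contrast-induced kidney injury, and bleeding. Established stratification
tools (GRACE, TIMI, Mehran, CRUSADE) each predict a different endpoint and
require many inputs. The Shock Index-C (SIC) combines three bedside
quantities into a single number:

$$\mathrm{SI} = \frac{\text{heart rate (bpm)}}{\text{systolic BP (mmHg)}},
\qquad
\mathrm{SIC} = 100 \cdot \mathrm{SI} - \widehat{\mathrm{CCr}},$$

where $\widehat{\mathrm{CCr}}$ is an estimated creatinine clearance from
the Cockcroft-Gault family. Tachycardia and hypotension raise the score;
preserved renal function lowers it. Higher SIC means higher risk.

### The creatinine-clearance variant

`creatinine_clearance()` defaults to the weight-free abbreviation

$$\widehat{\mathrm{CCr}} = \frac{140 - \text{age}}{\text{Scr}}
\times (0.85 \text{ if female}),$$

because a cohort with mean age near 61 and median creatinine 1.0 mg/dL
yields a mean CCr near 80 mL/min under this form, which is consistent with
the population the score was developed in. Whether the weight term and the
divisor 72 of the standard Cockcroft-Gault equation were part of the
original calculation cannot be settled from the printed formula alone, so
the full equation
$(140-\text{age})\cdot\text{weight}/(72\cdot\text{Scr})$ is available as
`variant = "full_cockcroft_gault"`. The two coincide exactly at
weight = 72 kg, which the test suite asserts.

### Stratification rules

- Tertiles at $-30$ and $-5$: T1 is $\mathrm{SIC} < -30$, T2 is
  $[-30, -5)$, T3 is $\ge -5$. The printed band "−30 to −5" does not say
  where ties land, so both cutpoints are left-closed on the upper stratum —
  a value of exactly $-30$ is T2, exactly $-5$ is T3. One rule, applied
  consistently, partitions the line with no gaps.
- Binary cutoff at 10, strict: the high-risk group is $\mathrm{SIC} > 10$;
  a patient at exactly 10 is low-risk, matching the published group sizes
  ($> 10$ vs $\le 10$).
- No rounding anywhere: stratification uses full-precision scores.

### The MACE composite

`derive_mace()` is positive when any of stroke, dialysis, acute heart
failure, or target-vessel revascularization occurred in hospital. Death is
deliberately *not* a component: the source tables account for death (68
events) and MACE (178 events) on separate rows, which is only coherent if
the composite excludes death. The composite is monotone in its components.

## The validation toolkit

Every statistic here is computed by the package itself; the tests check the
implementations against independent oracles (exhaustive pair enumeration,
hand-worked small examples, the pROC package, closed forms).

**Discrimination.** `auc_delong()` computes the Mann-Whitney AUC — the
probability that a random case outscores a random control, ties counting
one half — with the DeLong structural-component variance
$S_{10}/m + S_{01}/n$. `compare_auc_delong()` forms the paired contrast
$z = (A_a - A_b)/\sqrt{v_a + v_b - 2c_{ab}}$ with a two-sided normal
p-value; no small-sample correction is applied, which is appropriate for
cohorts of the size this pipeline targets (hundreds to thousands) and is
documented here rather than hidden. Scores whose association with the
outcome is protective (CCr) are sign-flipped by `evaluate_scores()` before
ROC analysis so that all AUCs are above one half, as clinical ROC software
conventionally reports them. `optimal_cutoff_youden()` maximizes
$J = \text{sens} + \text{spec} - 1$ and breaks ties toward the smallest
cutoff, preferring the more sensitive rule; the tie policy matters only on
degenerate curves but has to be fixed somewhere.

**Calibration.** A raw score is not a probability, so calibration is
assessed on the univariate logistic mapping
$\hat p = \text{logit}^{-1}(\alpha + \beta \cdot \mathrm{SIC})$ fitted by
`fit_logistic()` (IRLS, score equations solved to gradient norm $10^{-6}$;
perfect separation raises an error instead of returning divergent
coefficients). `hosmer_lemeshow()` then bins patients into g = 10
near-equal quantile groups — tied probabilities stay together, empty bins
merge with a warning — and uses the variance-corrected denominator
$E_g(1 - E_g/n_g)$ with $g - 2$ degrees of freedom. With 10 bins the
reference distribution has 8 df, which is the configuration consistent with
published chi-square/p pairs for this score. The simpler two-term
denominator is available via `correction = "simple"`.

**Reclassification.** The continuous (category-free) NRI is used because
no risk categories are defined for this score; any categorical NRI would
require inventing cutpoints. Ties move neither up nor down. The IDI is the
change in discrimination slope. Both get percentile bootstrap intervals
(default 1,000 resamples, seed 20100101) — the bootstrap is chosen over
asymptotic formulas because it makes no distributional assumption and is
exactly reproducible given `(seed, n_boot)`, which the tests assert
bit-for-bit. Note one algebraic fact the tests pin down: adding a constant
to every predicted probability moves all events up (+1) *and* all
nonevents up (−1), so the total NRI is 0 — the sum, not each component, is
shift-invariant.

**Decision curves.** `net_benefit()` computes
$NB(t) = TP/n - (FP/n)\,t/(1-t)$ on a default grid of 0.01-0.50 in steps
of 0.01 — the clinically plausible range of threshold probabilities for
acting on in-hospital mortality risk; nothing in the method constrains the
grid and callers can widen it. Classification at exactly $t$ is inclusive
($\hat p \ge t$), which changes TP/FP at probability ties and is therefore
documented. Raw scores are mapped through their univariate logistic fits
first so SI, CCr, and SIC compete on a common probability scale.

**Survival.** `kaplan_meier()`, `log_rank()`, and `cox_ph()` wrap the
survival package (survfit/survdiff/coxph) behind a uniform validated
interface. Ties are handled by the Efron approximation by default because
day-resolution follow-up produces tied event times; Breslow is available,
and the classical identity "two-group log-rank $\chi^2$ equals the Cox
score test at $\beta = 0$" is verified in the tests with Breslow ties,
where it holds exactly. The 1-year mortality clock starts at admission and
includes in-hospital deaths, with administrative censoring at 365 days.
The covariate set behind any adjusted hazard ratio is the caller's choice
(`covariates` argument): no published adjustment set exists for this score,
so hard-coding one would create false precision.

## The synthetic cohort generator

Real admission-level data for this population are not publicly deposited,
so `generate_cohort()` exists to make every pipeline stage testable. It
emulates the *marginal* structure of a contemporary STEMI-PCI cohort:

| quantity | default | source of the default |
|---|---|---|
| age | normal 61.4 ± 12.3 y, truncated to [18, 120) | published cohort mean ± SD |
| male fraction | 0.828 | published |
| heart rate | normal 80.2 ± 16.1 bpm, > 20 | published |
| systolic BP | normal 121.4 ± 22.0 mmHg, > 20 | published |
| weight | normal 65.3 ± 10.9 kg | published |
| serum creatinine | log-normal, $\mu = 0$, $\sigma = 0.3$, > 0.2 | matches median 1.0, IQR 0.8–1.2 mg/dL ($\sigma \approx (\ln 1.2 - \ln 0.8)/(2 \times 0.6745)$) |
| death / MACE / CI-AKI / bleeding prevalence | 0.037 / 0.096 / 0.100 / 0.104 | published event rates |
| AUC of SIC per outcome | 0.87 / 0.837 / 0.707 / 0.732 | published discrimination |

Outcomes are drawn from logistic links on the patient's SIC.
`calibrate_link()` finds the link deterministically: on a seeded pilot
sample of 50,000 covariate draws it computes the *expected* Mann-Whitney
AUC under independent Bernoulli outcomes (a smooth, monotone function of
the slope, evaluated in closed form on the sorted pilot scores) and solves
for the slope by root-finding, then sets the intercept to hit the target
prevalence. Monte-Carlo checks in the test suite show the resulting
empirical AUC at n = 20,000 is unbiased for the target to within sampling
noise (~0.005).

Two structural choices deserve emphasis:

- **Outcomes are conditionally independent given SIC**, except the MACE
  components. Drawing stroke/heart-failure/TVR/dialysis independently at
  their own prevalences would make the composite rate ≈ 0.11 rather than
  the published 0.096, because the real components co-occur. The generator
  therefore draws the *composite* from its calibrated link and then
  distributes component flags among composite-positive patients at the
  published conditional frequencies (23/178, 118/178, 12/178, 70/178),
  conditioned on at least one component firing, with the per-component
  probabilities solved by a fixed-point iteration so the conditional rates
  still match after that conditioning. Every published marginal is then
  reproduced in expectation, and `derive_mace()` agrees with the drawn
  composite by construction.
- **1-year survival** uses an exponential hazard
  $\lambda_i = \lambda_0 \exp(\gamma \cdot \mathrm{SIC}_i)$ with defaults
  $\lambda_0 = 8\times10^{-5}$/day and $\gamma = 0.032 \approx \log(8)/65$,
  chosen so the crude third-vs-first tertile hazard ratio lands near 8 —
  the magnitude reported for this contrast — given the ≈ 65-point spread
  between tertile means. This is illustrative, not inferential: it
  reproduces an effect size, not a fitted survival model. In-hospital
  deaths receive a follow-up time uniform on (0, 30] days.

What the generator does **not** emulate: covariate correlations (only
marginals are published; heart rate, blood pressure, and renal function
are certainly correlated in reality), derivation-vs-validation drift,
treatment variables, and any joint outcome structure beyond the MACE
composite. Consequently, passing tests demonstrate that the *pipeline*
computes its statistics correctly and that the generator meets its own
calibration targets — they do not validate the score on real patients.

## Numerical choices

- Ties in scores contribute ½ to the Mann-Whitney kernel; two scores with
  identical rankings give a zero-variance difference, reported as z = 0,
  p = 1 rather than 0/0.
- Percentages in event tables round half away from zero to one decimal
  (`round_half_up()`), the convention of clinical baseline tables; base R
  rounds half-even.
- Group comparisons use the chi-square test without continuity correction,
  falling back to Fisher's exact test when any expected cell count is
  below 5; two groups with zero events compare at p = 1.
- Logistic fits demand gradient norm < 1e-6 (IRLS tolerance 1e-12); Cox
  fits use eps = 1e-10 and reject coefficients beyond ±20 as monotone
  likelihoods.
- Bootstrap resamples that lose one outcome class are dropped from the
  percentile interval rather than imputed.

## Problem sizes in the test suite

The suite exercises the statistics at the sizes the methods are meant for:
exhaustive AUC oracle checks on 1,000 instances up to n = 200; Hosmer-
Lemeshow null calibration over 1,000 cohorts of n = 2,000; generator
self-consistency over 20 cohorts of n = 20,000; the SIC-vs-SI ordering over
100 cohorts of n = 1,851 (the published cohort size); Cox recovery at
n = 2,000. These sizes give Monte-Carlo error comfortably below the
assertion bands while keeping a full run to a few minutes.

## Known limitations

- The published headline numbers (AUC 0.877/0.868, Hosmer-Lemeshow 3.95
  and 5.01, NRI 37.0%, IDI 7.5%, cutoff sensitivity 82.4%/specificity
  77.8%, adjusted HRs) depend on the original patient-level data and are
  not recoverable from any synthetic cohort; the pipeline reproduces the
  published *rates* exactly from printed counts and the published
  *qualitative* ordering (SIC out-discriminates SI) distributionally.
- GRACE, TIMI, CRUSADE, and Mehran scores are defined in external
  publications and are not implemented; comparator scores enter as
  precomputed columns.
- No multi-category NRI, no recalibration methods, no competing risks, no
  time-varying covariates, no confidence bands on net benefit.
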