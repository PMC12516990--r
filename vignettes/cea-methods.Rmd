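---
title: "Methods: trial-based cost-effectiveness analysis with ceapipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis with ceapipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceapipe)
```

## The analysis this package implements

`ceapipe` is a pipeline for trial-based cost-effectiveness analysis (CEA)
of a remote person-centred care add-on intervention for people with
chronic heart failure (CHF) and/or chronic obstructive pulmonary disease
(COPD), evaluated against usual care in a two-arm randomised controlled
trial over a 2-year horizon. The estimand is the incremental
cost-effectiveness ratio

$$\mathrm{ICER} = \frac{\Delta C}{\Delta E}
  = \frac{\bar C_{\mathrm{int}} - \bar C_{\mathrm{ctrl}}}
         {\bar E_{\mathrm{int}} - \bar E_{\mathrm{ctrl}}},$$

with effects measured in quality-adjusted life years (QALYs) from
EQ-5D-3L responses and costs assembled from register-style
resource-use data under a societal perspective (healthcare + prescription
drugs + productivity loss + intervention delivery), with payer
(healthcare + drugs) and patient (out-of-pocket co-payments) perspectives
reported descriptively. When $\Delta E > 0$ and $\Delta C < 0$ the
intervention *dominates* and no ratio is reported — the result is the
dominance label plus the bootstrap cloud on the cost-effectiveness plane.

Because the trial's register microdata are confidential, the package is
built around its own synthetic-data module: every downstream stage is
specified, tested and exercised against generated registers whose
statistical structure matches what the analysis assumes.

## Effects: valuation, imputation, QALYs

**Valuation.** An EQ-5D-3L response is a 5-digit state (three levels on
five dimensions); a value set maps each of the 243 states to a utility
weight with full health at 1. Valuation is a pure lookup
(`value_state()`), independent of any cohort context. The published
Swedish experience-based and UK hypothetical tariffs are licensed tables
and are *not* shipped: analyses load them as 243-row text files
(`read_value_set()`). For testing the package provides a closed-form toy
set ($u = 1 - 0.1\sum_d(\ell_d - 1)$) and two `synthetic_*` stand-ins
that mimic only qualitative features (the experience-based set compressed
near full health; the hypothetical set wider, floored at $-0.594$).

**Multiple imputation.** Missing responses are multiply imputed on the
utility scale by chained-equations stochastic regression: each visit's
utility is regressed on arm, age, sex, diagnosis and the other visits'
utilities; missing cells receive draws $X\beta^* + e$ with $\beta^*$
from the approximate posterior of the fit and $e$ from the residual
distribution, cycling `maxit` times, for each of $m$ (default 20)
imputations. The contract — observed cells never altered, tables differ
only at missing cells, seed determinism, unbiased pooled estimates under
MCAR — is what the tests enforce; the engine behind it is replaceable.
Downstream estimates pool across imputations by Rubin's rules (for the
means reported here, pooling reduces to averaging). Visits scheduled
after a death are structural zeros, not missing data: they are neither
imputed nor counted. A patient with zero observed utilities cannot be
imputed from their own data; the pipeline default seeds their baseline
with the cohort baseline mean and logs a warning (configurable to
exclude or error).

**QALYs.** Utility is interpolated linearly between scheduled visits
(0, 3, 6, 12, 24 months) and integrated by the trapezoid rule — the
standard choice in trial-based CEA, adopted here because the source
analysis does not state its AUC method. Months 0–12 give year-1 QALYs;
months 12–24 give year-2 QALYs, discounted as a lump by $1/(1+r)$ with
$r = 3\%$/year by default. A patient who dies contributes utility 0 from
the death date, with a linear segment from the last observation down to
0 at death — again a convention the source leaves unstated, chosen for
being auditable and continuous. Closed forms anchor the tests: constant
utility 1 gives $1 + 1/1.03 = 1.970874$; a linear decline from 1 to 0
over 24 months gives exactly 1.

## Costs

All prices are in SEK at a fixed (2021-style) price level, deliberately
not inflation adjusted. Primary-care contacts are priced as multiples of
a physician consultation: 1.0 (physician), 0.4 (other HCP, group), 1.5
(team, group/team), 2.0 (home), 1/3 (indirect/telephone). Specialised
outpatient, inpatient and polyclinical episodes are priced as DRG weight
× average cost per DRG point; a missing specialised-outpatient weight
falls back to the multiplier method at the specialist consultation price,
while a missing inpatient/polyclinical weight is rejected as a data error
(those streams carry complete DRG information). Drug costs are summed ex
tax. Intervention delivery is HCP time (calls, documentation,
communication) × mean hourly wage including social contributions.
Productivity loss follows the human capital approach: absence days ×
daily wage for the patient's 10-year age band *at randomisation* (a
birthday crossing a band boundary mid-study does not change the band) ×
(1 + social contribution rate), zero for patients outside the labour
market. The daily wage is monthly wage × 12/365 unless overridden — a
day-count convention the source does not state.

The monetary unit prices shipped as defaults (SEK 1800 consultation,
SEK 3600 specialist, SEK 27,000 per DRG point, the wage table) are
placeholders with plausible magnitudes: the authoritative tariff
documents are cited but not printed in the source material, so real
analyses must supply their own `tariff()` configuration.

Events belong to study year 1 (days 0–364) or year 2 (days 365–729) by
their start day; inpatient episodes are assigned by admission day, not
split. Year-2 amounts enter discounted totals divided by $1+r$. Costs are
computed in exact double-precision SEK and rounded (half away from zero)
only at reporting.

## Patient co-payments

Co-payments are not registered and are therefore *simulated* from the fee
and ceiling rules, under the assumption that every patient's
reimbursement period starts at randomisation (so annual ceilings reset at
day 365): outpatient contacts pay a template fee (plus SEK 100 for
primary-care home visits; telephone contacts free) against an annual
SEK 1150 ceiling; hospital nights pay SEK 100 against a SEK 1500 ceiling
per 30-consecutive-day window, with a window opening at the first charged
night not covered by an open window; drug dispensations pay their
patient-payable amount against an annual SEK 2350 cap (the graded benefit
steps below the cap are intentionally not modelled — only the cap is).
Each engine is verified against a naive day-by-day simulator on ≥1000
randomised event streams, and property tests assert the ceilings are
never exceeded and that adding an event never decreases a cumulative
charge.

## Inference

Point estimates are arm mean differences on pooled per-patient
quantities. Uncertainty comes from a patient-level nonparametric
bootstrap: patients are resampled with replacement within arm (arm sizes
preserved), $(\Delta E, \Delta C)$ recomputed per replicate, and 95%
percentile intervals reported — percentile rather than BCa because the
source states only "bootstrapped confidence intervals". The bootstrap
resamples rows of the already-completed imputation tables (MI outside,
bootstrap inside would cost $m \times B$ imputations; the cheaper
ordering is the default and the calibration tests show nominal coverage
under the null). Baseline tables use Student's t (classic, per the
source's wording; Welch is a flag away), Pearson's $\chi^2$, and
Fisher's exact test by declared variable type, two-sided.

The harness runs the full analysis plan from one prepared dataset: base
case; sensitivity analyses (alternative value set, 5%/5% discounting,
effects undiscounted, 1-year horizon, per-protocol population,
complete-case); subgroups (survivors only, living alone, cohabiting);
payer and patient perspective views. Per-protocol keeps intervention
patients with at least one documented health-plan call and at least one
platform use, against the full control arm.

## The synthetic world

The generator states the world the pipeline is tested in; its defaults
were chosen once and are not tuned against test outcomes.

* **Cohort** (~the emulated trial's marginals): age $\sim N(70.7, 9.5^2)$,
  46.4% women, diagnosis mix 38/52/10 CHF/COPD/both, 30% living alone;
  labour-market participation 75% under 65, 4.5% at 65+. Stratified 1:1
  allocation within age band × diagnosis, per-stratum imbalance ≤ 1.
* **Utilities**: latent $u_{it} = b_i + s_a t + e_{it}$ with
  $b_i \sim N(0.80, 0.12^2)$, visit noise SD 0.08, control slope
  $-0.025$/yr and slope difference $+0.024$/yr (so the expected
  discounted 2-year QALY gap, $\approx 1.956 \times$ slope difference,
  matches the emulated headline of about 0.047). The latent value is
  truncated to $[-0.594, 1]$ and discretised to the nearest-valued
  EQ-5D-3L state under the active value set, which keeps an analytic
  oracle available: the expected observed utility is a sum of normal
  probabilities over the value-set grid.
* **Missingness**: MCAR per (arm, visit), baseline 4%, later visits 10%
  control vs 19% intervention — the source states only the ~2× arm ratio,
  so the levels are placeholders; a MAR switch tilts response probability
  on the logit scale by latent utility for imputation-mechanism studies.
* **Events**: homogeneous Poisson per care stream within each patient's
  time alive (rates ~10.5 primary, 6.8 specialised outpatient, 0.55
  inpatient admissions, 0.05 polyclinical, 25 dispensations per control
  year; intervention rate ratios 1.05/0.8/0.7/1.0/0.95), log-normal DRG
  weights, 23% missing weights in specialised outpatient only, exponential
  mortality at 0.06/yr, intervention contact time averaging ≈173 min per
  intervention patient.

What a green test establishes is therefore *internal* correctness —
estimators recover the generator's own parameters, engines match
brute-force oracles, the pipeline is deterministic — not agreement with
the confidential trial data. Real registers differ in ways the generator
does not emulate: correlated utilisation across streams, non-constant
hazards, skewed cost outliers (the emulated study's polyclinical
component was driven by a single surgical procedure), MNAR response
behaviour, and calendar-time effects.

## Numerical choices and edge cases

* Seeds: every stochastic stage derives its own child seed from the run
  seed (kept below $2^{31}$); reruns are byte-identical.
* Ties when discretising a latent utility break to the lower weight and
  then the lowest state code.
* $\Delta E = 0$ yields an undefined-ICER sentinel (`NA`) with label
  `undefined`; ratios are reported only in the two mixed quadrants.
* Monetary rounding is half away from zero, applied once at reporting;
  the 1/3 multiplier is kept exact internally.
* Degenerate inputs (empty event lists, zero-night admissions, all-zero
  probabilities, single-patient arms) are covered by tests rather than
  left to chance.

## Known limitations

* Unit prices, fee templates and wage tables are placeholder magnitudes;
  conclusions about absolute cost levels require user-supplied tariffs.
* The imputation model is linear on the utility scale; per-dimension
  level imputation is out of scope.
* CIs do not propagate MI between-imputation variance into the bootstrap
  (the MI-within-bootstrap ordering is the config-switchable remedy).
* Informal care, acceptability curves and net-benefit regression are out
  of scope, as in the emulated analysis.
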