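---
title: "Quantifying reverse-causation bias by multistate simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying reverse-causation bias by multistate simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcbias)
```

## The problem

Reverse-causation (protopathic) bias arises when a drug is prescribed for
early, still-undiagnosed symptoms of the very outcome under study.  The
motivating case: cutaneous T-cell lymphoma (CTCL) can present like atopic
dermatitis (AD) for years.  Patients whose CTCL is mislabelled as AD
respond poorly to first-line topical corticosteroids (TCS) and are
therefore channelled into the second-line drug, topical tacrolimus, shortly
before the correct diagnosis is made.  A cohort comparison of tacrolimus
versus TCS then shows an elevated CTCL hazard among tacrolimus users even
when neither drug affects the outcome at all.

`rcbias` quantifies this bias by construction: it simulates whole
populations under an exact null — treatment never changes the CTCL hazard —
runs a registry-style cohort analysis on the simulated data, and reads the
deviation of the estimated hazard ratio (HR) from 1 as the magnitude of the
reverse-causation bias.

## The multistate model

Every patient moves through the states *healthy* → (*TCS-treated* |
*tacrolimus-treated*) → *CTCL diagnosed*, with death/censoring possible
from any state.  Transitions are generated from latent event times, all
sampled by inverse transform so that the whole simulation is a
deterministic function of the random stream:

* **AD onset** `t_ad`: a calibrated mixture.  A patient becomes an AD case
  with probability 0.105; cases draw onset from an exponential childhood
  component (weight 0.63, mean 3.2 years) or uniformly over ages 18–100
  (weight 0.37).  The three constants are solved in closed form so the
  cumulative onset risk is 6.6% by age 18 and 10.5% by age 100, with a
  median onset age among cases of about 5 years — the anchors that define
  the intended marginal distribution.  The sampler is pluggable via
  `ad_onset_calibration()`; the nominal onset-rate constant
  `lambda_ad = 1.28e-6` is carried in `scenario_parameters()` for any
  alternative parametric sampler.
* **CTCL onset** `t_ctcl`: exponential with constant rate
  `lambda_ctcl = 6e-6` per person-year.  Over a 4-million-patient
  population followed to death this yields about 1,600 lifetime cases
  (analytically, `4e6 * E[1 - exp(-λ t_cens)]`).
* **Censoring/death** `t_cens = (1 - U²)·100`: a left-skewed law on
  [0, 100] years with mean 200/3, mimicking general-population mortality.
* **Diagnosis**: if AD comes first the patient is diagnosed with AD at
  `t_ad`.  If CTCL comes first, the initial diagnosis is correct with
  probability `p1`; otherwise the patient is *misdiagnosed with AD* at the
  CTCL onset age.  Misdiagnosed patients receive the corrected CTCL
  diagnosis after a delay `s2`, the **maximum of two** Weibull draws
  (shape 0.9, scale `lambda_reeval`); at the main-scenario scale 3.5 the
  delay has median 4.40 years (closed form:
  `reevaluation_delay_quantile(0.5)`).
* **Treatment**: first-line TCS with probability `p2`, else first-line
  tacrolimus.  TCS starters switch to tacrolimus with probability `p3`
  (true AD) or `p4` (misdiagnosed CTCL) after a nonresponse duration `s1`:
  40% of switchers take `1 - U²` years (below one year), the rest
  `1 + Exp(rate 3)` years.
* **No treatment effect anywhere**: neither drug enters any hazard.  Any
  HR away from 1 is bias.

The engine of the bias is the inequality `p4 > p3`: misdiagnosed patients
fail TCS more often, so tacrolimus use flags patients whose CTCL diagnosis
is already on its way.

### Numerical conventions

Events that never happen carry the sentinel age `never_age()` (`1e9`),
strictly greater than any attainable study age; a patient who never
switches keeps the censoring age as the "never reached" tacrolimus time, as
in the generating formulas.  Exact ties `t_ad == t_ctcl` have probability
zero; if they occur numerically the AD-first branch wins, so misdiagnosis
requires `t_ctcl < t_ad` strictly and `q = 0`.  `simulate_population()`
materialises only patients with some onset before censoring (about 11% of
the base population): a patient who stays healthy for their whole lifespan
can never be diagnosed, treated, or experience the outcome, so no
downstream quantity depends on them; the full base-population size is kept
as an attribute and enters the lifetime CTCL count.  Draws are consumed in
a documented fixed order so `(params, seed)` reproduces a population bit
for bit.

## The emulated cohort design

`build_cohort()` mirrors a multinational registry study: each patient gets
an administrative window starting at an inclusion age drawn uniformly on
[0, 100] years — independent of all latent times — and running for 12
years.  Patients enter at `max(inclusion age, AD diagnosis age)` (left
truncation: treatment starts at diagnosis, but person-time before the
window is unobserved) and exit at the earliest of window end, death, and
CTCL diagnosis.  Only strictly positive at-risk time qualifies; a CTCL
diagnosis coinciding exactly with the window end or death still counts as
an event (documented tie-break).  Correctly diagnosed CTCL-first patients
can never contribute: their CTCL diagnosis precedes any AD treatment.

`expand_counting_process()` lays follow-up out on the
time-since-treatment-initiation scale as `(start, stop]` rows with an
**ever-use** exposure flag: person-time before the tacrolimus switch is
TCS time, everything from the switch on is tacrolimus time, with no return
to the comparator.  A switch before study entry makes the whole record
exposed.  Person-time is conserved exactly by the split.

## Estimation

`fit_cox_td()` maximises the Cox partial likelihood for the single binary
time-varying exposure over these risk sets, respecting delayed entry.
Tie handling is Breslow: event times are continuous so genuine ties have
probability zero, and Breslow keeps the estimator identical to its oracle;
Efron weighting would differ only in the presence of ties.  The score
equation is solved by damped Newton iteration from 0 (score tolerance
1e-10, at most 50 iterations, steps capped at 5) and the standard error is
the inverse root of the observed information at the optimum.  Two
degeneracies are flagged as `converged = FALSE` rather than errors: a
monotone-separable exposure (the likelihood increases without bound; the
iteration is stopped at |log HR| > 20) and risk sets with no exposure
contrast (zero information).  Significance is the two-sided Wald test at
`alpha = 0.05` — what a standard Cox summary reports.

`estimate_incidence()` is the closed-form person-time estimator: events
divided by person-years within each exposure level, scaled to 1,000
person-years.  This is exactly the MLE of the Poisson model with log
person-time offset, so no iterative fit is needed (the identity is
asserted against a Poisson GLM in the tests).

## Replication and summaries

`run_setting()` derives two sub-seeds per replicate from the master seed up
front, so replicates are independent jobs whose results do not depend on
scheduling or execution order.  Each replicate simulates a fresh base
population (default 4 million patients), builds the cohort (roughly 2 ×
10⁵ patients, comparable to the adult cohort of the motivating registry
study), and records the HR, its Wald interval and p-value, and both
incidence rates.  Replicates with a non-converged fit are excluded from
the summaries and counted (`n_excluded`); at the default sample sizes this
is essentially never.

`summarize_setting()` reports the median, the 95% reference interval
(2.5th–97.5th percentiles, linear interpolation between order statistics —
the interval is insensitive to the percentile convention at 1,000
replicates), the min–max range, and the percentage of significant
replicates.  `render_outputs()` writes the two summary tables and one
histogram of the replicate HRs per setting with a logarithmic x axis,
since the HR distribution is right-skewed multiplicatively.

## Scenario grid

Fourteen built-in settings vary the five knobs:

| Group | Settings | What varies |
|---|---|---|
| main | A1–A9 | `p1` (0.25–0.75), `p2` (0.90–0.99), `p3` (0.05–0.20), `p4` (0.10–0.40) around the base tuple (0.25, 0.95, 0.05, 0.25, λ = 3.5) |
| max-use | B1–B3 | doubled tacrolimus use (`p2` = 0.90, `p3` = 0.20, `p4` = 0.40), `p1` 0.25–0.75 |
| discovery | C1–C2 | faster correct diagnosis, λ = 1.2 and 0.5 |

Any field can be overridden through `load_scenario_config()`, which is how
the null-recovery checks (`p1 = 1`, or `p3 = p4`) are expressed.

```{r, eval = FALSE}
params <- builtin_setting("A1")
res <- run_setting(params, n_replicates = 100, master_seed = 7)
summarize_setting(res)
```

## Problem sizes used by the test suite

The published summaries are medians over 1,000 replicates of 4-million
patient populations.  The package's own checks use desk scales chosen to
keep every comparison inside its Monte-Carlo tolerance: 100 replicates at
the full 4-million population for the headline settings A1, B1 and B3 and
for the null-recovery checks (the Monte-Carlo standard error of the median
HR at 100 replicates is about 0.07 for A1); 200 replicates at a 400,000
population for the ten-setting bias-ordering checks, whose tolerance is
computed from the replicate spread itself.  Null recovery deliberately
stays at full population size: with very small cohorts, replicates whose
events all fall in one exposure group are excluded as non-converged, which
asymmetrically trims the low tail of the HR distribution and would shift
the median away from 1 for reasons unrelated to the bias mechanism.

## What the generator does and does not emulate

The generator reproduces the structural mechanism — shared symptoms,
misdiagnosis, differential switching, delayed correct diagnosis, ever-use
exposure, left truncation — under clean conditions: no confounding, no
treatment effect on any hazard, an age-constant CTCL rate, independent
censoring, and an inclusion age independent of health history.  Passing
checks therefore demonstrate the magnitude of bias this mechanism alone
can produce in an idealised registry; they do not bound the bias in real
data, where confounding, age-varying cancer incidence, informative
censoring, exposure misclassification and lag-time analyses all coexist.
No matching, covariate adjustment or lag-window sensitivity analysis is
implemented, mirroring the design under study.

## Known limitations

* The AD-onset law is a calibrated reconstruction from its published
  anchors, not a verbatim published formula; the sampler is pluggable
  should the exact form be needed.
* The re-evaluation-delay law is validated on its closed-form median (and
  the equivalent lower quartile); other quantiles of the published
  description are internally inconsistent and are not asserted.
* `p_short_switch` defaults to 0.40 (40% of switchers below one year of
  TCS), following the narrative description of the switch process; the
  tabulated indicator weighting reads as the complement and is available
  by setting `p_short_switch = 0.60`.
* The Cox fit handles exactly one binary covariate — the design under
  study — not general regression.
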