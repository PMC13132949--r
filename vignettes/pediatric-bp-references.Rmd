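---
title: "Methods: pediatric oscillometric BP reference values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pediatric oscillometric BP reference values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedbpref)
```

## The model

Pediatric office blood pressure has no outcome-based cut-off; the
hypertensive range is defined *distributionally*, as BP at or above the
95th percentile of healthy same-age, same-sex children. `pedbpref` builds
such reference distributions by **quantile regression**: for each outcome
(systolic, diastolic), each sex, and each level $\tau$ on the grid
$0.05, 0.10, \dots, 0.95$, the conditional quantile is modelled as linear
in age,

$$Q_{\tau}(\mathrm{BP} \mid \mathrm{age}) = \beta_{0,\tau} + \beta_{1,\tau}\,\mathrm{age},$$

with $\hat\beta_\tau$ minimising the check loss
$\sum_i \rho_\tau(y_i - x_i'\beta)$, $\rho_\tau(u) = u(\tau - 1\{u<0\})$.
Modelling each quantile separately — rather than assuming a location-scale
family — lets the *spread* of BP move with age independently of the
median, which is exactly the observed behaviour of systolic BP in
childhood (widening spread with age) and the reason a single linear
regression with Gaussian bands would understate upper percentiles in
adolescents.

Assumptions worth stating explicitly:

* each conditional quantile is linear in age over 4–15 years (no spline
  smoothing of centiles; the supporting model ladder below is there to
  check that flexibility is not needed);
* children are exchangeable within sex and age (no household clustering —
  see limitations);
* the analysis population is the *included, normal-weight* subset: weight
  status is classified before fitting and overweight children are kept in
  the cohort but excluded from reference estimation.

### The supporting model ladder

`compare_models()` reproduces the standard modelling audit: adjusted $R^2$
from linear regressions of mean BP on age, height, sex and their
combinations, restricted cubic splines (3 knots at the predictor's
quartiles, giving one nonlinear degree of freedom) as a linearity check,
and a quantile-level comparison of the **full** (age + height z-score) and
**simple** (age) models at $\tau = 0.95$: the mean/maximum mmHg shift of
the predicted 95th percentile across the 5th–95th height percentile span,
and the fraction of full-model positives the simple model recovers. This
is the evidence base for dropping height from the final model in an
ethnically homogeneous population.

### Classification and concordance

Any of three reference representations can classify a child: a printed
lookup table (categories only — interpolating three printed columns would
invent precision), a US-style Gaussian polynomial
($\mu = \alpha + \sum_j \beta_j(\mathrm{age}-10)^j + \sum_k \gamma_k z_h^k$,
percentile $= 100\,\Phi((\mathrm{bp}-\mu)/\sigma)$), or a fitted quantile
set. Guideline rules switch from the percentile cut-off to fixed mmHg
thresholds at an age boundary (AAP: 13 y, 130/80; ESC: 16 y, 130/85;
ESH: 16 y, 140/90; boundaries inclusive, positivity is systolic *and/or*
diastolic). Agreement between a benchmark and a comparator is summarised
by the 2×2 reclassification table, detection rate $100a/(a+b)$, false
negative/positive rates $100b/n$, $100c/n$, per-age 95th-percentile
differences in mmHg, and Bland–Altman limits of agreement
(mean $\pm\ 1.96\,$SD of differences, $n-1$ denominator).

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `taus` | – | 0.05–0.95 by 0.05 | the 19-point grid the reference is reported on |
| `percentiles` | % | 50, 90, 95 | the columns printed in pediatric reference tables |
| `ages` | years | 4–15 | integer rows of the emitted table |
| `sds_cutoff` | z | derived | overweight = the centile through BMI 25 kg/m² at 18, computed from the supplied BMI reference, not hard-coded |
| WHtR cut-off | – | 0.5 | overweight proxy when weight is missing, boundary inclusive |
| `acceptable_detection` | % | 85 | screening-policy default, configurable, never hard-coded into logic |
| `within_visit_sd` | mmHg | 3 | **assumed**, not estimated: the device's within-visit SD is not published. 3 mmHg is a realistic oscillometric repeatability figure; tests that compare against closed forms set it to 0 |
| `overweight_rate` | – | 0.146 | the published cohort's 1771 − 1512 overweight fraction |
| `missing_weight_rate` | – | 0.035 | the published missing-weight rate |

Generator BP defaults (intercepts ≈ 90/60 mmHg, age slopes ≈ 1.4/0.45
mmHg·y⁻¹, systolic residual SD ≈ 6.3–7.4 + 0.11·age mmHg, diastolic SD
constant at 4.9 mmHg) were calibrated *once* from the published centile
table (median and 95th percentile at ages 4 and 15 per sex) and are not
revisited; height means/SDs track a Scandinavian growth reference with
per-age SDs inside the reported 3.6–8.5 cm band.

## What the synthetic generator does and does not emulate

It **does** reproduce: uniform continuous age on [4, 16) (so "age 15"
means 15.0–15.99 completed years); Gaussian BP conditional on age and sex
with heteroscedastic systolic spread; triplicate readings = true BP +
independent within-visit noise, rounded to integer mmHg; per-sex LMS
anthropometry with an optional height effect knob (`height_beta`, mmHg per
height z, default 0); overweight fraction pinned exactly by a two-part
mixture around the derived cut-off; missingness and register-flag rates;
deterministic per-variable sub-streams (adding a flag never perturbs BP
draws).

It does **not** emulate: household sampling and participation rates,
within-family correlation, seasonal or observer effects, digit preference
beyond integer rounding, correlation between BP and adiposity (BP depends
on age, sex and optionally height z only), or real register code logic
(exclusions enter as pre-drawn booleans). A green test on synthetic data
therefore establishes that the *pipeline computes its estimands
correctly*, not that the defaults describe any real population.

## Numerical choices

* **Quantile solver.** No linear-programming backend is assumed:
  `fit_quantile()` runs a Hunter–Lange MM iteration (weighted least
  squares with weights $1/(|r|+\varepsilon)$ and the linear
  $(2\tau-1)$-term, $\varepsilon$ shrunk from $10^{-2}$ to $10^{-9}$ of
  the outcome scale), then polishes exactly by enumerating the
  $p$-subsets of the $p+6$ smallest-|residual| observations (an optimal
  basic solution interpolates $p$ points). Tests verify the achieved loss
  against grid-search minima; any minimiser on the optimal face is
  accepted.
* **Non-crossing.** Fitted quantile curves may cross between taus; the
  table builder sorts predicted values across the tau grid at each
  evaluation age (isotonic rearrangement) — minimal intervention, exactly
  testable, no refitting.
* **Rounding.** Table entries round half away from zero (printed-table
  convention), not banker's rounding; unrounded values are retained in an
  attribute. Percentages in reclassification output follow the same rule.
* **Quantile definition.** Spline knots use the linear-interpolation
  sample quantile (type 7) — stated because quantile definitions differ.
* **Percentile interpolation.** For quantile-set references,
  `percentile_of()` takes the largest grid tau whose predicted quantile is
  ≤ bp, interpolates linearly to the next tau, and clamps to [2.5, 97.5]
  outside the grid — no extreme-tail claims beyond the fitted range. Flat
  segments (ties after rearrangement) resolve to the largest qualifying
  tau.
* **Age coding for lookup tables.** Completed years (floor), switchable to
  nearest-integer; integer table rows are evaluated at the exact integer
  age (age 10 row = model at 10.0), not mid-year.
* **Degenerate inputs.** Empty cohorts flow through; a single reading is
  its own mean; rank-deficient designs fail naming the collinear columns;
  a reclassification with no benchmark positives reports NA rather than
  erroring.

## Open design decisions (and why)

* **Sex-stratified fits** rather than a pooled model with a sex term: the
  published table's sex-specific divergence with age cannot come from a
  parallel-shift sex term; stratification reproduces it and costs little
  at these n. Pooled-with-covariate fitting remains available through
  `fit_quantile()` directly.
* **Exclusion precedence** is fixed (data availability, medication,
  diagnosis, origin) so logs are deterministic; the order follows the
  usual flow-chart convention of listing availability first.
* **Bland–Altman pairs** compare the two models' 95th-percentile values
  per (age, sex) stratum, not per-child percentiles: the model-vs-model
  question is the one the mmHg-gap analysis asks; a per-child variant is a
  one-liner on `percentile_of()` output if wanted.
* **US-model coefficients ship as external JSON**, with clearly labelled
  *synthetic* stand-ins packaged for tests and demos: the genuine
  coefficient sets are third-party appendix data and the machinery must
  not depend on sourcing them.
* **Reading order is authoritative** for the last-two-of-three mean;
  readings are never re-ordered by value.

## Limitations

Single-visit screening distributions, not diagnostic thresholds; no
ambulatory or auscultatory validation layer; no inferential statistics on
agreement (kappa, McNemar) by design; quantile fits assume linearity in
age per tau; the simple-vs-full detection fraction is an *estimate* whose
sampling noise at tau = 0.95 is visible at cohort sizes of ~10⁴ (the
height coefficient's SE translates to ~0.2–0.4 mmHg threshold jitter near
the 95th percentile, flipping a few per cent of the positives even when
the true height effect is zero — see the acceptance notes in the test
suite).
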