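---
title: "Compositional analysis of 24-hour movement behaviours and well-being: methods"
author: "coda24h"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of 24-hour movement behaviours and well-being: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coda24h)
```

## The scientific problem

A day is a closed budget: the minutes spent asleep (TST), sedentary (SB), in
light physical activity (LPA) and in moderate-to-vigorous physical activity
(MVPA) must sum to 1440. Time-use epidemiology therefore cannot treat these
behaviours as independent exposures — increasing one necessarily decreases
others — and ordinary regressions of an outcome on raw minutes are
confounded by the constraint. `coda24h` implements the standard
compositional-data-analysis (CoDA) answer for the 4-part movement-behaviour
day, with mental well-being (the 14-item Warwick-Edinburgh Mental Well-being
Scale, WEMWBS, scored 14–70) as the outcome of interest:

1. epoch-level accelerometer streams are reduced to one daily time-use
   vector per participant (non-wear detection, sleep scoring, cut-point
   classification, valid-day filtering, averaging, closure to 1440 min);
2. compositions are mapped to $D-1 = 3$ unconstrained isometric log-ratio
   (ILR) coordinates and entered in ordinary linear models with staged
   covariate adjustment;
3. the fitted model is interrogated by *compositional isotemporal
   substitution*: the predicted well-being difference when $t$ minutes are
   reallocated from one behaviour to another at a reference composition.

## The model

For a composition $x = (x_{TST}, x_{SB}, x_{LPA}, x_{MVPA})$, the pivot ILR
coordinates under a sequential binary partition (SBP) are

$$ z_i = \sqrt{\frac{r_i s_i}{r_i + s_i}}
   \ln \frac{g(\text{numerator parts})}{g(\text{denominator parts})}, $$

where $g(\cdot)$ is the geometric mean and $r_i, s_i$ count the numerator
and denominator parts of SBP row $i$. The pivot SBP contrasts one part
against all remaining parts in its first row, then drops it and promotes
the next part; `sbp_pivot(4, k)` rotates the part order cyclically so each
behaviour can occupy the pivot. The outcome model is

$$ y = \beta_0 + \beta^\top z(x) + \gamma^\top c + \varepsilon, $$

with $c$ the covariates of the chosen adjustment stage: model 1 none;
model 2 age, sex, education, marital status, professional activity; model 3
additionally smoking and chronic conditions. Fitting is ordinary least
squares (`lm()`); classical homoskedastic standard errors are reported, as
is conventional in this literature, and the overall model fit is summarised
by $R^2$ and the overall F-test p-value.

Because the four pivot rotations span the same column space, fitted values,
residuals, $R^2$ and the F statistic are identical across rotations; only
the coordinate *labels* change. `behaviour_betas()` exploits this: for each
behaviour it refits with that behaviour as pivot and reports the first
coordinate's coefficient — the association of time in that behaviour
*relative to all others*. A consequence worth knowing: the four reported
first-pivot coefficients are linear images of one 3-vector and always sum
to zero.

**Units.** Coefficients are reported per unit ILR, the only scale on which
they are well defined. Describing them as "per hour" is a common shorthand
in applied reports but is not exact: a one-hour change in a behaviour does
not correspond to a fixed change in any single ILR coordinate. The
substitution interface below is the principled way to express effects in
minutes.

## Isotemporal substitution

`substitute_time()` computes, at a reference composition $x_0$ (by default
the sample geometric mean of the analysed participants, the standard choice),

$$ \hat\Delta(t) = \big(z(x_{t}) - z(x_0)\big)^\top \hat\beta, $$

where $x_t$ moves $t$ minutes from the donor to the recipient behaviour and
leaves the others untouched. Covariates are held at any fixed value — they
cancel exactly in the difference, so no covariate-averaging scheme is
needed. The confidence interval is the delta-method interval
$\hat\Delta \pm t_{1-\alpha/2,\,\nu}\sqrt{d^\top \hat\Sigma d}$ with
$d = z(x_t)-z(x_0)$, $\hat\Sigma$ the ILR block of the coefficient
covariance and $\nu$ the residual degrees of freedom; for a linear model
this coincides with the difference of predictions at the two compositions.
At $t = 0$ the estimate and interval are identically zero. Estimates are
invariant to which pivot rotation was used for fitting (a basis change).

`substitution_grid()` evaluates all 12 ordered behaviour pairs over 5–60
min in 5-min steps (144 cells per model). Cells where $t$ meets or exceeds
the donor's reference minutes are reported as missing with a reason, never
clipped or dropped: with a small MVPA share at the reference this happens
well inside the 60-min grid, and silently clipping would bias any summary
of the grid.

## Accelerometer preprocessing

The preprocessing stage is deliberately generic and fully parameterised,
because the vendor algorithms usually cited for wear-time validation and
sleep/wake scoring do not have their parameter sets printed in applied
reports:

* **Non-wear**: an epoch is non-wear iff it lies in a run accumulating at
  least `window_min` minutes of zero counts, allowing embedded non-zero
  interruptions of at most `spike_tolerance_min` minutes each (defaults 90
  and 2 — the common run-length rule for count data). Tolerated spikes
  inside a qualifying run are non-wear too.
* **Sleep**: a centred, odd-length weighted moving window over the counts;
  an epoch is asleep when the weighted sum falls below a threshold. This is
  the functional form of the classical actigraphic scorers; weights and
  threshold live in the config so a published parameter set can be
  supplied. Edges are padded by repeating the boundary epochs.
* **Cut-points**: sedentary iff $\mathrm{VM3} \le$ `sb_upper`, light iff
  $\le$ `lpa_upper`, MVPA above; both bounds inclusive on the lower
  category. The shipped values (1853, 3940 counts/min) are *illustrative*
  wrist-VM3 values, not a validated set; studies must substitute their own.
* **Hierarchy**: non-wear dominates sleep, which dominates the cut-points.
* **Valid day**: at least 600 min (10 h, inclusive) of waking wear time
  (SB+LPA+MVPA; sleep does not count). Participants need at least 4 valid
  days; behaviour minutes are averaged over valid days *first* and the mean
  vector is then closed to 1440 min, yielding one composition per
  participant as the regression unit. Days are calendar-aligned
  (midnight-to-midnight); partial first/last days are dropped, which is
  unambiguous for whole-day accounting under a multi-day wear protocol.

Zero handling follows the usual CoDA practice: `check_zeros()` reports
zeros per part; when present, `replace_zeros()` applies multiplicative
replacement (zeros to `delta` = 1 min by default, non-zero parts rescaled
so the total is preserved). The closure tolerance used in round-trip
checks is $10^{-9}$ relative.

## The synthetic cohort generator

No participant-level data are distributed with the package, so every stage
is exercised on synthetic cohorts whose defaults emulate published summary
statistics for a community-dwelling 55+ cohort ($n = 410$):

* **Compositions** are logistic-normal: ILR vectors drawn from a
  multivariate normal centred at the ILR of the geometric-mean composition
  (5.65, 13.88, 2.58, 1.89 h of TST/SB/LPA/MVPA — these published hours sum
  to exactly 24.00) and inverted to the simplex. The ILR covariance is
  derived from a target pairwise log-ratio variation matrix via the centred
  log-ratio covariance $\Gamma = -\tfrac12 G T G$. Only the extreme
  published entries are available (0.103 for TST–SB, 0.550 for LPA–MVPA);
  the four intermediate entries (0.28, 0.42, 0.24, 0.38) were chosen once
  as plausible values inside that range, ordered so that MVPA is the least
  co-dependent part, and verified to give a positive-definite ILR
  covariance. The conversion is exact: the expected sample variation
  matrix equals the target.
* **Outcome**: $y = \beta_0 + \beta^\top z + \gamma^\top c +
  \mathcal N(0, \sigma^2)$, rounded to an integer and clamped to the
  WEMWBS range [14, 70]. The default $\beta$ is the ILR vector whose four
  first-pivot images are the published unadjusted per-behaviour
  coefficients $(-2.17, -0.43, 1.96, 0.64)$ — these sum to zero, exactly as
  one consistent coefficient vector requires (for $D=4$,
  $b_k = \tfrac{2}{\sqrt3} a_k$ links a pivot coefficient to its clr
  counterpart). $\beta_0$ is set so the expected score is 53.75 and
  $\sigma$ is derived as $\sqrt{8.43^2 - \beta^\top\Sigma\beta}$ so the
  marginal SD matches 8.43. Rounding and clamping attenuate the realised
  mean and SD by a few percent at most (clamping touches ≈2% of scores at
  the top of the scale); recovery tests tolerate this mild attenuation.
* **Covariates** are drawn independently of the composition from the
  published category frequencies (71% female, education 45/32/20,
  77% married/cohabitant, 95% professionally inactive, 3% smokers, chronic
  condition 39/54/7 yes/no/missing; age $\mathcal N(71.3, 6.3^2)$ truncated
  to [55, 95]). By default they carry no outcome effect and do not
  confound; `confound = TRUE` makes age and sex shift the compositional
  mean, which is used to test that adjustment moves the estimates.
  "Missing" chronic status is a real category in the data and becomes `NA`
  only when chronic enters the model (model 3), reproducing listwise
  deletion there and only there.
* **Epoch streams**: `simulate_epoch_stream()` lays each day out as a sleep
  block (small non-zero counts, below the sleep-score threshold but
  breaking zero runs), then SB/LPA/MVPA blocks with counts drawn inside
  the respective cut-point bands. The only classification slack is at the
  sleep–wake boundary, where the moving window straddles both regimes, so
  the pipeline recovers the target minutes to within a few minutes per
  behaviour per day (tests assert ±5). Short-wear days insert a 700-min
  zero block, failing the 10-h rule; giving a participant three such days
  exercises the 4-valid-day exclusion. The streams are *not* realistic
  diurnal waveforms — counts are piecewise-stationary blocks — so passing
  round-trip tests demonstrates the correctness of the classification
  logic, not validity of the default parameters on real devices.

## What the tests do and do not show

The test suite checks the algebra (closure, ILR round-trips and isometry
against a brute-force Aitchison distance, variation-matrix and OLS oracles,
pivot invariance to $10^{-9}$), the statistical calibration of the modelling
chain on generated cohorts (coefficient recovery within 2 SE in ≥93 of 100
cohorts of $n=410$; first-pivot type-I error within [0.035, 0.065] over
1000 null cohorts), and the end-to-end epoch-stream round trip. Problem
sizes — cohorts of 100–410, $10^3$–$10^4$ draws for distributional checks —
were chosen to make Monte-Carlo error small relative to the tested margins
while keeping the default suite fast. None of this validates the
preprocessing defaults against real accelerometer recordings, and the
generator's independence of covariates and composition (without
`confound`) is an idealisation real cohorts will not satisfy.

## Numerical choices and edge cases

* Natural logarithms throughout; the closure total (1440 min) and part
  order (TST, SB, LPA, MVPA) are fixed package-wide, and pivot rotations
  are expressed through `pivot`, never by reordering columns.
* Cut-point and valid-day boundaries are inclusive (`<=` on the upper
  category bound; 600 min exactly is a valid day; 4 valid days exactly is
  included).
* Rank-deficient designs error out naming the offending columns, including
  the small-sample case where a rare covariate category (professionally
  active, 4%) is unobserved and the factor collapses.
* Confidence intervals use the $t$ distribution with the fit's residual
  degrees of freedom, not normal quantiles.
* The 11-row fixture cohort cannot support model 3's 12-column design;
  fixture-based invariance checks use models 1–2, and full-model checks use
  generated cohorts.

## Limitations

Cross-sectional modelling only: no longitudinal or bidirectional
structure. One-to-one reallocations only: reallocating one behaviour's
time to all others simultaneously is out of scope. Proprietary device
formats are not parsed; the pipeline starts from epoch CSVs. WEMWBS item
responses are summed without psychometric modelling, and no imputation of
missing items is offered.
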