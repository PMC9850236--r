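---
title: "Cold-season mortality, distributed lags, and particulate modification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cold-season mortality, distributed lags, and particulate modification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coldmod` estimates how cold temperature raises daily mortality over a
window of following days, and how fine (PM2.5) and submicronic (PM1)
particulate matter modifies that risk. This vignette explains the model,
the design, the estimator, the synthetic-data generator used to validate
everything by parameter recovery, and the numerical choices a maintainer
would want to know about.

## The model

Each death is treated as a case in a **time-stratified case-crossover**
design: the days of the same calendar month and year that share the death
day's weekday serve as its referent (control) days. Because exposure is
compared within this small stratum, everything constant over a month —
age, sex, lifestyle, season, long-term trend, day-of-week structure — is
conditioned out with the stratum constant.

Within a stratum the log-odds of a day being the death day is modelled as

```
logit P = alpha_stratum + cb(Temp) + ns(RHma, df = 3) + PM + cb(Temp) * PM
```

* `cb(Temp)` is a **DLNM crossbasis**: a natural cubic spline over
  temperature (3 df, internal knots at equally spaced quantiles of the
  cold-season temperatures, boundary knots at the observed range) crossed
  with a natural cubic spline over lags 0–12 days (4 df, intercept
  included, internal knots log-spaced in `log(lag + 1)`). Row `t`, column
  `(j, k)` holds `sum_l R_j(temp[t - l]) C_k(l)`, so the 12 coefficients
  describe a full exposure–lag–response surface.
* `ns(RHma, 3)` adjusts for the lag 0–12 moving average of relative
  humidity.
* `PM` is the lag 0–12 moving average of the chosen pollutant (one model
  set per pollutant), entered linearly.
* `cb(Temp) * PM` — every crossbasis column multiplied by the PM moving
  average — lets the whole temperature surface shift with pollution. The
  interaction is parameterised on raw (uncentred) PM; centring is applied
  at prediction time, which gives identical curves.

The fitted coefficients are reduced to:

* the **cumulative exposure–response curve**: log-OR of temperature `x`
  vs a reference, summed over lags, `a(x, ref)' beta`, with
  `a[(j,k)] = (R_j(x) - R_j(ref)) sum_l C_k(l)` and delta-method standard
  errors;
* the **MMT** (minimum mortality temperature): argmin of that curve on a
  0.1 °C grid from the observed 1st percentile to the observed maximum
  (reference-invariant; ties break warm);
* the **extreme-cold OR**: the curve at the 1st percentile of cold-season
  temperature vs the MMT;
* **modified curves** at pollutant level `p`, using effective
  coefficients `beta + p * gamma` and covariance
  `V_bb + p^2 V_gg + 2 p V_bg`, evaluated at the 10th/50th/90th
  percentiles of the daily pollutant concentrations (low/median/high);
* the **percent change per 10 µg/m³**: with `delta = a' gamma`,
  `100 * (exp(10 * delta) - 1)`, CI from `se = sqrt(a' V_gg a)` on the
  log scale.

All CIs are computed on the log scale with the 1.96 normal quantile and
exponentiated, so they are asymmetric around the OR.

### Why the lag basis has an intercept

A natural-spline basis without an intercept vanishes at its left boundary,
which would force the lag-0 effect to zero by construction — exactly the
opposite of cold effects, which are typically strongest on the first days
of exposure. The lag dimension therefore spends one of its `df` columns on
an intercept (so 4 df means 2 internal knots); the temperature and
humidity bases remain intercept-free because the conditional likelihood
absorbs constants into the stratum term.

## The estimator

The weighted conditional-logistic log-likelihood

```
sum_s w_s * (eta_case(s) - log sum_{d in s} exp(eta_d))
```

is maximised by Newton–Raphson from the zero vector with step-halving,
converging on a score max-norm below 1e-8 (with a relative
likelihood-stall fallback for very large weighted counts, where an
absolute 1e-8 is below floating-point resolution). The covariance is the
inverse observed information; a sandwich option exists. Deaths sharing a
region, day and analysis subgroup share the same exposures, so they are
aggregated into one stratum with a count weight — this is exact, and the
test suite verifies it against fully expanded per-death strata and against
`survival::clogit`.

Columns with no within-stratum variation anywhere (variance below 1e-12 in
every stratum) are aliased with the stratum constants; they are dropped,
reported, and returned as `NA` coefficients. Singular information and
non-convergence surface as errors — there is no silent regularisation.

Strata touching any day with an incomplete covariate (missing exposure or
insufficient lag history) are dropped whole and counted; the accounting is
attached to the design and checked (`input = used + dropped`) on every
run.

## The synthetic-data generator

The generator exists so every stage can be tested by parameter recovery
without any confidential registry data. Its defaults emulate the study
region's cold season (November–February, six seasons, one region,
400 deaths/day at reference conditions):

* **Temperature**: stationary AR(1) within each season block, mean
  1.17 °C, marginal SD 4.34 °C, lag-1 coefficient 0.65 — matching the
  reported median 1.17 (IQR −1.49, 4.37) °C.
* **PM1 / PM2.5**: log-normal with medians 51.78 and 81.34 µg/m³ and
  log-scales matching the reported IQRs; their log-deviations follow an
  AR(1) with coefficient 0.9 within seasons (winter particulate episodes
  persist for days; an iid series would leave its 13-day moving average
  with almost no within-month contrast and make the interaction
  practically unidentifiable at these sample sizes), correlated 0.8
  between the two size fractions, and coupled negatively to temperature
  (−0.03 per °C: colder days are more polluted). The temperature–PM
  coupling is a free modelling choice — the source material reports no
  such correlation. No day-wise PM1 ≤ PM2.5 constraint is imposed, since
  the two pollutants are analysed in separate model sets.
* **Humidity**: truncated normal in [0, 100], mean 55, SD 15. **Ozone**:
  independent log-normal, median 50 µg/m³.
* **Deaths**: Poisson per day and demographic subgroup with log-rate
  `cb' beta* + theta * PMma + PMma * cb' gamma*`, centred so the baseline
  is the expected count with the temperature history held at the MMT and
  PM at its median. Subgroup shares follow the study population's
  composition (55.97% male; 55.90% aged ≥ 75; 89.62% lower education with
  5.14% missing; 64.08% cardiorespiratory), and subgroup-specific
  interaction strength is configurable for stratified-recovery tests.
  Records are emitted aggregated by (date, region, subgroup) — exact for
  this likelihood — with an expansion helper for per-death rows.
* **Lead-in**: each season block carries 21 exposure days before
  November 1 so every in-season day (and every referent of an early-
  November case) has a complete 12-day lag history. Deaths are only
  generated for season days.

Everything is driven by one integer seed with deterministic child streams
per component (weather, PM, ozone, deaths), so a configuration reproduces
byte-identically.

### Calibrating the truth

`calibrate_surface()` expresses the generative truth in the estimator's
own spline family, so recovery tests measure estimator correctness, not
approximation error (a deliberately misspecified quadratic-surface mode is
available for robustness exploration, and is not used in acceptance
checks). The cumulative temperature shape is a hockey stick — a log-linear
cold limb meeting a quadratic warm-side upturn that regains half the cold
effect at the observed maximum — projected onto the temperature basis
under the constraint that the projected curve is stationary at the
requested MMT. The lag profile is front-loaded (`exp(-lag / 3)`,
normalised) projected onto the lag basis. The projection is then scaled so
the cumulative contrast at the observed 1st temperature percentile equals
`log(target OR)` exactly (round-trip verified to 1e-8), and the
interaction vector so the same contrast equals `log(1 + pct/100)/10` per
µg/m³ — or, in paired mode, so the modified ORs at the pollutant's 10th
and 90th percentiles hit two prescribed values.

Two shape choices deserve comment, both made during design and frozen:

* A symmetric quadratic around the MMT looks natural but projects onto a
  3-df natural spline as a curve whose minimum is flat to within ±0.005
  over ±2 °C — the MMT of such a truth is unidentifiable at any realistic
  sample size. The hockey-stick elbow is both the field's standard
  description of cold effects and what makes a minimum estimable.
* The default true MMT sits at 8 °C, the 94th percentile of the simulated
  temperatures. The study's reported MMT lies above the warm end of the
  region's cold-season temperature distribution; a truth placed in that
  far tail cannot be represented (the calibration raises an error, since
  the spline family has no curvature capacity where there are no data),
  and estimated curve minima there wander enough to bias the extreme-cold
  OR upward through minimum selection. The MMT-recovery study instead
  uses a warm-region regime (mean 17 °C, SD 4 °C) whose observed maximum
  exceeds 19 °C, placing the true MMT of 18.5 °C inside the data bulk.

### What the generator does not emulate

Real registry data bring spatial exposure heterogeneity across ~1,800
sub-districts, measurement error in modelled PM surfaces, demographic
drift, holidays, influenza epidemics, and reporting artefacts. None of
these are simulated; the generator produces one (or a handful of)
independent regions with exact exposures. Passing recovery tests therefore
demonstrates that the pipeline estimates what it claims to estimate under
its own assumptions — not that those assumptions hold in any particular
registry.

## Problem sizes and tolerances

The validation suite uses the study's reference conditions (six seasons,
400 deaths/day, ~350k deaths per replicate, about one second per
simulate-plus-fit cycle): 20 replicates for overall-effect and MMT
recovery, 5 for modification recovery, and 100 smaller replicates (three
seasons, 100 deaths/day) for the null-modification coverage study. Under
the reference conditions a single fit carries a sampling SD of roughly
0.07 on the extreme-cold OR, ~0.45 °C on the MMT, and ~4 percentage
points on the PM1 percent-change-per-10 — so single-fit recovery checks
are read as bias checks on replicate means, while coverage checks use the
per-replicate CIs. Oracle comparisons are exact: crossbasis rows against
direct double-loop summation at 1e-12, conditional-logistic MLEs against
brute-force maximisation at 1e-6, spline spaces against a truncated-power
construction at 1e-8.

Other numerical conventions: percentile thresholds (P1 temperature,
pollutant centering levels) use type-7 linear-interpolation quantiles over
in-season region-days; centering levels are percentiles of the *daily*
pollutant series (back-calculation from the headline estimates shows this
is the convention under which an OR span of 1.60–2.20 across P10–P90 and
~8% per 10 µg/m³ are mutually consistent); curve grids use 0.1 °C steps;
the common reference for all modified curves is the MMT of the curve at
the median pollutant level; MMT ties break toward the warmer temperature.

## Known limitations

* No multi-region pooling (multivariate meta-analysis is out of scope);
  regions are fitted jointly with shared coefficients.
* No heat-season analysis, attributable-fraction computation, or
  PM-component decomposition.
* The MMT is reported without a confidence interval, as is conventional;
  its sampling noise is visible in the recovery studies.
* The conditional-logistic path assumes one case day per stratum with
  count weights; other referent schemes (symmetric ±7 days, full-month
  strata) are not implemented.
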