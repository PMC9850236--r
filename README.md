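# coldmod

Cold-temperature mortality risk and its modification by particulate
matter: a time-stratified case-crossover analysis with distributed lag
non-linear models (DLNM), in R.

## The problem

Cold spells kill, and they kill with a delay: a cold day raises mortality
over roughly the following two weeks. Air pollution may amplify that risk
— days that are both cold and polluted can be deadlier than either hazard
alone, and smaller particles (PM1) may modify the cold effect more
strongly per unit mass than PM2.5. Quantifying this requires (i) a
flexible model for the non-linear, lagged temperature–mortality
relationship, (ii) a design that removes confounding by season, trend and
day-of-week, and (iii) an interaction structure that lets the whole
temperature surface shift with pollutant concentration.

`coldmod` is written for environmental epidemiologists who want that
pipeline as tested, composable R functions: tibbles in, tibbles out,
`autoplot()` for every result type, `tidy()`/`glance()` for fitted
objects.

## The model

Each death day is compared with the same weekdays of the same calendar
month and year (time-stratified case-crossover, bidirectional referents).
Within stratum *i*,

```
logit P = alpha_i + cb(Temp) + ns(RHma, 3) + PM + cb(Temp) * PM
```

where `cb(Temp)` is the crossbasis of a natural cubic spline in
temperature (3 df) with a natural cubic spline in lag 0–12 days (4 df),
`RHma` and `PM` are lag 0–12 moving averages, and the interaction crosses
every crossbasis column with the PM moving average. The conditional
likelihood (one case per stratum, death counts as weights) is maximised
by Newton–Raphson; the fitted surface is reduced to a cumulative
exposure–response curve, the minimum mortality temperature (MMT), the
extreme-cold OR (1st temperature percentile vs MMT, lag 0–12), curves
centred at low/median/high pollutant levels (10th/50th/90th percentiles),
and the percent change in the extreme-cold OR per 10 µg/m³:
`100 * (exp(10 * a'γ) − 1)` with delta-method CIs.

Because the underlying mortality registry is not public, the package
ships a calibrated synthetic-data generator (`sim_config()`,
`simulate_study()`): cold-season temperature and correlated PM1/PM2.5
series matching the study region's reported quantiles, and Poisson deaths
under a known exposure–lag–response surface, so every estimate is
validated by parameter recovery. See the methods vignette
(`vignettes/cold-pm-dlnm.Rmd`) for the full account.

## Worked example

Simulate six cold seasons in which the true extreme-cold OR is 1.60 on
low-PM1 days and 2.20 on high-PM1 days, then fit the PM1 model set:

```r
library(coldmod)

cfg <- sim_config(seed = 7,
                  truth = true_surface_spec(or_low = 1.60, or_high = 2.20))
sim <- simulate_study(cfg)
report <- run_analysis(sim$deaths, sim$exposures, analysis_config("pm1"))
report
#> Cold effect (PM1 model set): MMT 8.1 C; OR at -7.4 C: 1.90 (1.80, 2.00)
#> Extreme-cold OR by PM1 level (ref 8.1 C):
#>   level       pm       or conf_low conf_high
#>     low 32.80887 1.615436 1.441113  1.810846
#>  median 52.28563 1.897086 1.795320  2.004620
#>    high 73.84684 2.266491 2.083051  2.466085
#> Percent change per 10 ug/m3: 8.6 (4.2, 13.2)
```

Reading this: the fitted curve attains its minimum at 8.1 °C (the true
MMT was 8.0 °C); at the 1st temperature percentile (−7.4 °C) mortality
odds are 1.90 times the minimum at the median PM1 level. The modified ORs
at the 10th and 90th PM1 percentiles recover their calibrated truths
(1.60 and 2.20), and each 10 µg/m³ of PM1 raises the extreme-cold OR by
8.6% (95% CI 4.2, 13.2; the implied truth in this simulation is 8.1%).

`glance(report)` returns the same numbers as a one-row tibble;
`autoplot(report)`, `autoplot(report$lag)` and
`autoplot(report$modification)` draw the exposure–response curve, the
lag-response pattern and the centred ORs. `run_stratified()` repeats the
fit by sex, age group, education and cause of death;
`run_sensitivity()` re-runs it across maximum lags 10–18, alternative
knots, a 4-df humidity spline and ozone adjustment. `write_study()` /
`read_study()` round-trip the simulated tables as `exposures.csv` and
`deaths.csv`.

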