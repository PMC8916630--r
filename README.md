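# crthresh

Monte Carlo assessment of how **classical exposure measurement error**
degrades the detectability of a **threshold** in chronic-risk
concentration-response (C-R) functions, in the setting air-pollution
epidemiology actually works in: city-structured survival cohorts analysed
with Cox proportional-hazards models.

Most long-term PM2.5 cohort studies have not detected a C-R threshold, and
risk analyses consequently tend to assume none exists. `crthresh` builds the
counterfactual laboratory for that inference: cohorts whose mortality
*truly* follows a hockey-stick C-R function, observed through exposure
records corrupted by a known amount of classical error, and analysed with
the standard toolkit. Because the truth is known by construction, the
package measures directly how often the threshold survives the analysis.

## The model

Each of 100 cities enrols 20,000 males aged 60, followed for 20 annual
cycles (2 million individuals). A survivor of city *j* dies in year *t*
with probability

    P_jt = min{ 1,  B_t * h^max(0, PM_j - T) }

where `B_t` is the life-table baseline annual death probability at age
60 + t, `h` the hazard ratio per µg/m³ and `T` the true threshold (the
hinge `max(0, PM - T)` makes the C-R flat below `T`, log-linear above).
Observed exposure is `PM_j + e`, `e ~ N(0, σ²)` truncated at ±4 µg/m³.
For every scenario on the factorial grid — T ∈ {7, 8.5, 9.5} µg/m³,
h ∈ {1.0025, 1.005, 1.01, 1.02, 1.05}, σ ∈ {1, 2, 4} µg/m³ — and each of
100 error replicates, the package:

* fits Cox models with the true-threshold hinge covariate and with
  untransformed observed PM, on the aggregated city-year counts (Breslow
  ties make the 2-million-person partial likelihood an exact function of
  100 × 20 cells);
* compares them by `S = 2·(LL_threshold − LL_null)` against the AIC (2) and
  BIC (`ln n`) one-parameter penalties — non-nested models, so no LR test;
* grid-searches the best-fitting threshold over T ± 4 µg/m³ in 1 µg/m³
  steps;
* checks whether the best fit's 95% CI upper limit falls below the true
  hazard ratio (attenuation), and fits natural-spline relative-risk
  diagnostics.

## Worked example

One full-scale scenario — true threshold 8.5 µg/m³, hazard ratio 1.05,
error SD 1 µg/m³, 100 error replicates:

```r
library(crthresh)
sched  <- interpolate_schedule(default_life_table(), 1940, 60, 20)
cities <- generate_true_exposures(100, seed = child_seed(1, "exposure"))
errs   <- draw_error_sets(100, sigma = 1, n_sets = 100,
                          seed = child_seed(1, "errors:1"))
block  <- run_scenario(cr_scenario(8.5, 1.05, 1), cities, sched, errs,
                       experiment_config(seed = 1))
block$detect
#>             aic      bic_deaths bic_individuals
#>             100             100             100
block$best_freq
#>  4.5  5.5  6.5  7.5  8.5  9.5 10.5 11.5 12.5
#>    0    0    0    6   91    3    0    0    0
```

All 100 replicates prefer the threshold model even under the most stringent
penalty (`2·ΔLL > ln 2,000,000 ≈ 14.51`), and the grid search recovers the
true 8.5 µg/m³ threshold in 91 of 100 replicates, with the misses landing on
the adjacent candidates — at σ = 1 the threshold is still clearly visible.
A single replicate's true-threshold fit shows the attenuation already at
work:

```r
obs <- observe(cities$true_pm, errs$errors[1, ])
out <- simulate_cohort(cities, sched, cr_scenario(8.5, 1.05, 1), 20000,
                       seed = child_seed(1, "cohort:8.5,1.05,1"))
cox_fit(out, effective_pm(obs, 8.5))
#> Cox PH fit (breslow ties), aggregated city-year counts
#>   beta = 0.041496 (se 0.000453)  HR = 1.04237 [1.04144, 1.04330]
#>   partial logLik = -12864953.417, converged in 4 iterations
```

The true `ln h = ln 1.05 ≈ 0.0488` is attenuated to 0.0415, and the CI
already excludes the truth. Raising σ pushes detection counts down, the
estimated threshold location down, and the estimated HR further toward 1 —
run the factorial grid to see the full pattern:

```r
cfg <- experiment_config(scale = "desk", seed = 1)   # 2,000/city, 25 reps
res <- run_grid(cfg, progress = TRUE)
tb  <- build_tables(res)
tb$detection      # detection counts per criterion and scenario
tb$best_freq      # best-threshold frequency matrices (rows sum to 25)
tb$coverage       # CI-below-true-HR counts
```

A thin CLI wraps the same functions:
`Rscript inst/cli/crsim.R run --seed 1 --scale desk --out out/`.

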