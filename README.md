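# immunospline

Derivative-based smoothing-spline inference for immune aging: how do
absolute immune cell counts (cells/µL of whole blood) change across the
adult lifespan, and do women and men change differently?

The package is written for immunologists and biostatisticians analyzing
cross-sectional cytometry cohorts — one row per participant with age,
sex, and absolute counts (or frequencies plus a total leukocyte count)
for each leukocyte population — who want age-resolved answers without
pre-defined age groups or parametric age terms.

## The method

For each population the mean count is modelled as a **cubic smoothing
spline** in age: the minimizer of

$$\sum_i w_i\,(y_i - f(x_i))^2 + \lambda \int f''(t)^2\,dt$$

over natural cubic splines with knots at every distinct age.  Smoothing
is set through the scale-free parameter `spar` (default 0.8, a
deliberately conservative choice) via
λ = r·256^(3·spar−1) with r the trace ratio of the basis
cross-product to the second-derivative penalty matrix on the rescaled
design.

Inference rides on the **first derivative** f′(Age), the instantaneous
rate of change in cells/µL per year: f′ > 0 means rising counts, f′ < 0
falling.  Uncertainty comes from a **nonparametric case bootstrap**
(default 2000 replicates): whole participant records are resampled with
replacement, the spline refit with the same `spar`, and pointwise 95%
percentile bands formed on a 1-year age grid.  Age ranges where the
derivative band excludes zero are the **significant changes**.

Sex is handled by stratified fits and two contrasts, each with its own
stratified-bootstrap band:

* **level difference** E₍female₎(Y|Age) − E₍male₎(Y|Age) — who has more
  cells at a given age;
* **derivative difference** f′₍female₎(Age) − f′₍male₎(Age) — the
  age × sex interaction: who is changing faster at a given age.

A synthetic-cohort generator (117 women, 114 men, integer ages 19–93,
composable mean trajectories, mean-preserving overdispersed noise)
provides ground truth for the calibration and recovery checks.

## Worked example

```r
library(immunospline)

# a cohort with a known sigmoidal decline: 600 -> 300 cells/µL,
# centred at age 55, lognormal noise (sigma = 0.4)
sim   <- simulate_cohort(scenario_logistic_decline(seed = 1))
pairs <- cohort_subset(sim$cohort, "logistic_decline")

fit <- fit_smoothing_spline(pairs$age, pairs$count, spar = 0.8)
fit
#> Cubic smoothing spline fit
#>   observations: 231 (72 distinct ages, 19.0-93.0 years)
#>   spar = 0.8, lambda = 0.003647, edf = 6.64

band <- bootstrap_band(pairs, statistic = "derivative",
                       n_boot = 2000, seed = 1)
band
#> Bootstrap derivative band (95%, 2000 replicates, percentile intervals)
#>   grid: 19-93 (75 ages); dropped replicates: 0

extract_significant_regions(band)
#> # A tibble: 1 × 4
#>   statistic  start_age end_age direction
#>   <chr>          <dbl>   <dbl> <chr>
#> 1 derivative        50      70 decrease
```

Reading the output: the fitted mean uses ~6.6 effective degrees of
freedom over 74 years of age; the derivative band excludes zero on ages
50–70, so counts decline significantly there — bracketing the true
inflection at 55.  (The fitted curve at 55 is 466.9 cells/µL against a
true 450.)  Heavy smoothing attenuates peak slopes, so detected windows
for smooth declines are indicative, not sharp.

For the sex analyses, `sex_contrast()` returns the per-sex fits, the
level-difference and derivative-difference bands, and their significant
regions in one call; `run_pipeline()` drives any set of analyses over
all populations of a cohort and writes band/region TSVs, a
population × age sex-difference matrix, and figures.  The numbered
scripts under `analysis/` walk a four-population synthetic study
through exactly these steps (simulate → overall trajectories → sex
differences → interaction).

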