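---
title: "Smoothing-spline trajectories and derivative inference for immune aging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoothing-spline trajectories and derivative inference for immune aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunospline)
```

## The question and the model

Cross-sectional immunophenotyping cohorts ask how absolute immune cell
counts (cells/µL of whole blood) change over the adult lifespan, and
whether women and men age differently.  Classical approaches bin
participants into age groups or impose a parametric age term; both
prejudge where change happens.  `immunospline` instead models the mean
count nonparametrically,

$$
Y_i = f(\mathrm{Age}_i) + \varepsilon_i ,
$$

with \(f\) a **cubic smoothing spline**: the minimizer of

$$
\sum_i w_i \bigl(y_i - f(x_i)\bigr)^2 \;+\; \lambda \int f''(t)^2\,dt
$$

over natural cubic splines with knots at every distinct age.
Inference is then carried by the **first derivative** \(f'(\mathrm{Age})\),
the instantaneous rate of change in cells/µL per year: \(f' > 0\) means
counts are rising at that age, \(f' < 0\) falling.  An age range is
called a significant change when the 95% confidence band of \(f'\)
excludes zero throughout the range.

Two sex contrasts complete the picture, both computed on the age grid
shared by the two sexes:

* the **level difference** \(E_{\text{female}}(Y\mid\mathrm{Age}) -
  E_{\text{male}}(Y\mid\mathrm{Age})\), answering *who has more cells at
  a given age*;
* the **derivative difference** \(f'_{\text{female}}(\mathrm{Age}) -
  f'_{\text{male}}(\mathrm{Age})\), the age-by-sex interaction on the
  rate-of-change scale, answering *who is changing faster*.  A band for
  this difference that excludes zero at some ages is evidence that the
  sexes age at different rates there.

## Smoothing: spar, lambda, and the adopted conventions

The penalty weight \(\lambda\) is not interpretable across designs, so
smoothing is controlled through the scale-free parameter `spar` via

$$
\lambda \;=\; r \cdot 256^{\,3\,\mathrm{spar} - 1},
\qquad
r = \frac{\operatorname{tr}(X^\top W X)}{\operatorname{tr}(\Omega)} ,
$$

with the basis cross-product \(X^\top W X\) and the exact
second-derivative Gram matrix \(\Omega\) computed after rescaling ages
to \([0,1]\), and the traces summed over the interior basis functions.
This is the convention of the standard R smoothing-spline
implementation, so `spar = 0.8` — the package default — produces the
familiar, deliberately conservative degree of smoothing that keeps
bootstrap refits from chasing wiggles.  Cross-validated smoothing is
deliberately *not* the default: the bootstrap refits each resample with
the **same** `spar`, and per-replicate smoothing selection would both
destabilize the bands and answer a different question.

Numerical choices worth knowing:

* **Knots at every distinct age, no thinning.**  With cohort sizes near
  230 and integer (survey) ages this is at most ~75 knots; exactness of
  the penalized solve is what the engine's oracle tests pin down
  (agreement with a dense brute-force solve of the penalized normal
  equations to better than 1e-8 relative).
* **Duplicate ages** are collapsed to one knot carrying the weighted
  mean response and summed weight — algebraically identical to fitting
  the raw rows.  Ages closer than `1e-6 ×` the age span are treated as
  duplicates.  This also keeps the design well conditioned: knot gaps
  below ~1e-5 of the span push penalty entries toward 1e14 and would
  degrade any solver.
* **The penalty matrix is exact**, assembled by Simpson's rule per
  inter-knot interval (the integrand, a product of piecewise-linear
  second derivatives, is piecewise quadratic, so the rule is exact).
* **λ = 0** is solved as the natural interpolating spline (minimum
  roughness subject to exact fit), the correct \(\lambda \to 0^+\)
  limit; the all-knots basis has two more functions than knots, so the
  unpenalized normal equations alone would be singular.
* **Derivatives are analytic**, evaluated from the B-spline coefficients
  with the chain-rule correction for the age rescaling; units are
  cells/µL per year.
* **Extrapolation is refused by default.**  A natural spline continues
  linearly beyond the boundary knots; `extrapolate = TRUE` enables
  exactly that extension, and bootstrap refits use it, since a resample
  can miss the extreme ages of the full sample.

## The bootstrap bands

Sampling uncertainty is propagated by the **nonparametric case
bootstrap**: whole (age, count) participant records are resampled with
replacement — within sex for the contrasts, so every replicate keeps the
design's group sizes — and the spline is refit to each of `n_boot`
replicates (default 2000, as in the motivating analysis) with the same
`spar`, evaluating curve and derivative on the same 1-year grid.
Pointwise **percentile** intervals across replicates form the band;
`interval_type = "basic"` switches to reflected (basic) intervals for
sensitivity analysis.  The bands are pointwise, not simultaneous:
significance is read age by age, which matches the "band excludes zero
at these ages" interpretation but means the family of ages is not
jointly error-controlled, and no multiplicity correction is applied
across populations either.  Replicates whose resample has fewer than 4
distinct ages are redrawn (up to 100 times, then dropped and counted) —
a non-event at cohort sizes above ~100.

Reproducibility is structural: every replicate owns a pre-assigned seed
derived from the master seed (keyed by group label for the contrasts),
so results are identical no matter how the replicate loop is executed
(serially or across forked workers), and swapping the order of the two
group labels negates the difference statistics *exactly*.

Regions are extracted as maximal runs of consecutive grid ages where the
band's lower limit exceeds zero (increase) or upper limit falls below
zero (decrease); single-age runs are reported as one-point regions.

## The synthetic cohort and what it does (not) show

No individual-level cohort data ship with the package, so calibration
and recovery are demonstrated on simulated cohorts with known truth.
The generator mirrors the motivating study design: 117 women and 114
men, integer ages drawn uniformly on 19–93 (an optional middle-weighted
distribution mimics sparse age tails), population means given by
composable trajectories (constant, linear, logistic decline, piecewise
linear, Gaussian bump, sums, per-sex overrides), and strictly positive
overdispersed noise.  The default noise is mean-one multiplicative
lognormal with σ = 0.4 — right-skewed, variance growing with the mean,
a realistic stand-in for cytometry counts; negative binomial and
zero-truncated Gaussian alternatives are included.  Ground truth
(curves, derivatives, and their exact sign regions) is tabulated on a
0.01-year grid directly from the trajectory functions, never from the
inference under test.

The scenario library fixes one scenario per acceptance property: a flat
null, the logistic decline (600 → 300 cells/µL centred at 55, width 8)
used for coverage, a piecewise decline of −8 cells/µL/year on ages
40–75, a female level shift, and a sex-divergent slope (female −8 vs
male 0 on ages 20–60).  Baseline levels, which neither the study nor
the method pin down, were chosen once at realistic leukocyte-subset
magnitudes (500–700 cells/µL).

What passing these checks shows: the engine solves the stated
optimization exactly; the bands attain close to nominal pointwise
coverage at an interior age under a smooth truth; flat truths are
flagged at about the nominal error rate; and strong monotone declines
are localized with substantial overlap of the true window.  What they
do **not** show: real cytometry counts have measurement error,
batch/panel effects, and age distributions the generator only
caricatures; smoothing at `spar = 0.8` widens sharp onsets (a kink in
the true trajectory is recovered as a gradual shoulder, so detected
regions bleed a few years beyond sharp true boundaries); and the
interaction statistic, being a difference of two derivative estimates
from half-size groups, carries roughly twice the standard error of a
pooled derivative — at the default cohort size, a −8 cells/µL/year
divergence is detected only partially in a typical run.  Simulated
recovery there is reported honestly rather than presented as a solved
problem.

## Problem sizes used in the shipped checks

The package's own test suite runs the coverage experiment at 200
simulated cohorts with 500 bootstrap replicates each, the null
calibration at 40 cohorts, the two recovery experiments at 20 seeds
each, and one full 35-population pipeline at the default 2000
replicates — sizes chosen to make the Monte-Carlo error small relative
to the acceptance margins while keeping a complete run on one CPU
comfortable.  The analysis scripts under `analysis/` use the full 2000
replicates throughout.

## Known limitations

* Pointwise bands only; no simultaneous bands, no BCa intervals, and no
  analytic (sandwich or Bayesian) spline uncertainty.
* Counts are fitted on their raw scale by default; if a log-scale
  analysis is wanted, transform explicitly — nothing is transformed
  silently.
* Each participant is one cross-sectional observation; repeated
  sampling waves, covariates (BMI, season), and within-person
  trajectories are out of scope.
* Interpreting age trends as within-person change assumes the
  age–count relationship is stable across birth cohorts, which
  cross-sectional data cannot verify.
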