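---
title: "Provenance choice for a stage-structured tree cohort in a warming climate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Provenance choice for a stage-structured tree cohort in a warming climate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agflow)
```

## The question

Even-aged forestry plants a cohort of seedlings after a clearcut and
harvests it decades later. Under climate warming the cohort experiences a
moving temperature during its life, so the seed source ("provenance")
adapted to the planting-year climate is generally not the one that
maximises survival to harvest — but a provenance adapted to the harvest-year
climate suffers while young. `agflow` quantifies this trade-off and finds
the provenance whose thermal optimum maximises the expected number of trees
in the final stage at harvest.

## Model and assumptions

The cohort has $n$ discrete stages. Each year an individual in stage $i$
survives with probability
$s_i(\theta, T_t) = s_{i,\max}\, e^{-(\theta - T_t)^2 / 2\omega_i^2}$
and, conditional on survival, advances one stage with probability $g_i$.
The model assumes:

* **One optimum per tree, for life.** $\theta$ is a provenance property;
  stages differ in tolerance *width* $\omega_i$, not in their optimum.
* **No retrogression or stage-skipping**, and no reproduction: we track a
  single planted cohort, so total abundance only declines.
* **No density dependence.** Empirical matrices are taken to embed
  competition at realistic planting densities.
* **Vital rates are at their optimum in the data.** Decomposing an
  empirical matrix into $(s_{i,\max}, g_i)$ assumes the measured
  population sat at its thermal optimum; mismatch then only scales
  survival down.
* **Expectation dynamics.** `project_cohort()` iterates expected
  abundances (Equation-style matrix projection); demographic stochasticity
  of individuals is not simulated. Life-*history* stochasticity (the random
  ages of transition) is handled exactly, by mixing the fixed-history
  closed form over all feasible histories.

For a fixed life history $\vec a$ the expected harvest is Gaussian in
$\theta$ with mode $T_{tot}$ (yearly temperatures averaged with weights
$\omega_{tot}^2/\omega_i^2$) and width $\omega_{tot}$, where
$\omega_{tot}^2 = (\sum_i d_i/\omega_i^2)^{-1}$ over the stage durations
$d_i$. One textual statement of this aggregation elsewhere reads as
$\omega_{tot}^2 = \tilde\omega^2 H$; we implement the inverse-sum form,
which is the one consistent with the constant-tolerance special case
$\omega_{tot} = \omega/\sqrt H$.

## Time indexing

Selection acts in years $t = 1,\dots,H$ with $T_t = T_0 + kt$: the first
year a seedling faces is already one step into the warming trend, and the
planting-year temperature ($t = 0$) enters nothing. A consequence worth
knowing: with constant tolerance the best provenance is the mean of the
series, $T_0 + k(H+1)/2$, not $T_0 + kH/2$.

## Parameters, units, defaults

| Parameter | Meaning | Default / presets | Why |
|---|---|---|---|
| $H$ | rotation length (yr) | 60 (100 variant) | mid-range stand rotation |
| total warming | °C over 60 yr | 0 / 1.7 / 2.6 / 3.3 | end-of-century multi-model projections (control, SSP2-4.5, SSP3-7.0, SSP5-8.5); presets are quoted per 60 years whatever $H$ |
| $\sigma_f$ | interannual sd (°C) | 0.35 / 0.5 / 0.65 | observed local year-to-year sd ≈ 0.5 °C, ±30% for model spread |
| $\omega_{tot}$ | cumulative tolerance (°C) | 2 / 3.5 / 5 | narrow / intermediate / wide climatic niche, the plausible order of magnitude from provenance-trial survival data |
| $b$ or $\omega_n/\omega_1$ | tolerance ontogeny | $b \ge 0$ in simulation presets | juveniles are typically the less tolerant stage; negative $b$ is allowed analytically |
| grid | candidate $\theta$ | $[T_0, T_0+4]$ step 0.01 °C | covers every deterministic scenario's lifetime mean; widened to $[T_0-5, T_0+5]$ for fluctuation runs |
| replicates | ensemble size | 100 | stabilises mean and sd of $\theta^*$ at the 0.01–0.02 °C level |

Calibration holds $\omega_{tot}$ fixed while $b$ varies: `calibrate_omega1()`
solves the aggregation identity for $\omega_1$ on the *typical* life history
(fundamental-matrix expected stage durations, rounded up to whole years).
This makes ontogeny scenarios comparable within and across life cycles.

## Numerical choices

* **"Rounded to the next integer"** for typical transition ages is
  implemented as `ceiling()` (with a $10^{-9}$ guard against floating-point
  spill); ties after rounding are bumped up by one year to keep ages
  strictly increasing.
* **Grid ties** are broken toward the cooler provenance — the conservative
  translocation — and a maximum on a grid boundary raises a warning.
* **Quarter-rotation snapping** rounds halves away from the baseline
  (toward warmer), then snaps to the grid step: a projected offset of
  +0.425 °C reads +0.43 °C.
* **Enumeration cap.** The life-history mixture enumerates
  $\binom{H}{n-1}$ histories; beyond a cap (default $2 \times 10^5$) the
  identical expectation is computed by matrix projection instead.
  `harvest_over_grid()` exploits the bidiagonal projection structure to
  evaluate all grid candidates simultaneously.
* **Variable cohorts.** The Gaussian-within-cohort closed form (variance
  $\sigma_p^2$ adds to $\omega_{tot}^2$, with a
  $\omega_{tot}/\sqrt{\omega_{tot}^2+\sigma_p^2}$ prefactor) was derived as
  the Gaussian–Gaussian convolution and is validated against adaptive
  quadrature to $10^{-8}$ relative error in the tests. The variance is the
  variance of $\theta$ itself.
* **Effective cumulative tolerance.** The calibration anchors on the
  unconditional typical history, while survivors realise other histories,
  so the realised response width can exceed the target. How to measure that
  excess is genuinely open; we define it operationally as the curvature of
  a quadratic fit to log expected harvest across the provenance grid under
  a constant climate. Under this definition the excess vanishes exactly
  when growth is deterministic, and tracks the gap between the
  fundamental-matrix typical age and the survivor-weighted age — it is
  *not* monotone in growth-timing variance, so we do not assert that.
* **Conformance.** Matrices with fecundity, retrogression or skips can be
  cleaned (`policy = "drop"`); removed mass becomes extra mortality and is
  never renormalised into remaining transitions, which is the conservative
  reading. Both strict and drop policies are surfaced, with a per-column
  report, because source databases do not document a canonical treatment.

## What the synthetic generators emulate

`two_stage_example()` is the canonical slow-maturation conifer-like cycle
(juvenile survival 0.61, adult survival 0.98, growth 0.012/yr).
`random_life_cycles()` draws vital rates uniformly on (0.01, 0.99) and
applies the same reachability filter used for empirical matrices (the
typical history must reach the last stage by harvest).
`species_like_matrix()` constructs $n$-stage cycles pinned to a target
first-stage duration, standing in for real species that differ mainly in
how long the youngest — typically least tolerant — stage lasts; files it
writes are labelled synthetic. What these fixtures do **not** emulate:
correlations among vital rates across stages found in real matrices,
stage definitions that vary between data sources, reproduction, and any
climate variable other than one temperature axis. Tests passing on these
fixtures therefore validate the *mathematics* of the method, not
species-specific predictions.

## Known limitations and edge behaviour

* At integer transition ages the "return" of the optimum toward the
  constant-tolerance value as the juvenile stage shrinks is incomplete:
  with one juvenile year and $\omega_2/\omega_1 = 9$, that single year
  still carries $81/(81+59) \approx 58\%$ of the lifetime-temperature
  weight, leaving the optimum several tenths of a degree cool of the
  series mean. The continuous-age limit is only approached for rotations
  of thousands of years. The opposite end (juvenile stage filling almost
  the whole rotation) does converge.
* A last transition exactly at harvest ($a_{n-1} = H$) is accepted; the
  final-stage survival product is then empty.
* Fluctuations are drawn independently each year (no autocorrelation);
  an autocorrelated generator would slot into `temperature_series()` but
  is deliberately not a default.
* Multi-dimensional climate niches, stage-specific optima, thinning and
  reproduction are out of scope.

## Problem sizes used by the test-suite

The suite runs the two-stage cycle over the full 60-year rotation (and a
100-year variant), a three-stage cycle over 12 years for cross-engine
equivalence, 100-draw random-cycle panels for the algebraic identities and
the soft placement check, and paired 100-replicate fluctuation ensembles —
sizes chosen so every check completes in seconds while leaving the
Monte-Carlo assertions with comfortable standard-error margins.

```{r}
cycle <- two_stage_example()
history <- typical_life_history(
  fundamental_matrix(rebuild_matrix(cycle$vital)), cycle$H
)
scenario <- climate_scenario(T0 = 10, H = 60, total_warming = "intermediate")
omega <- calibrated_profile(3.5, history, ratio = 3)
fit <- best_provenance(cycle$vital, omega, temperature_series(scenario),
                       provenance_grid(10))
glance(fit)
compare_strategies(cycle$vital, omega, scenario)
```
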