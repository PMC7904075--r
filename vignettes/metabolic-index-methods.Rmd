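---
title: "Methods: calibrating and mapping the metabolic index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrating and mapping the metabolic index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phimap)
```

## The model

The metabolic index compares the oxygen a habitat supplies with the oxygen a
resting fish demands:

$$\phi = \frac{pO_2}{pO_{2,\mathrm{crit}}(T, B)}, \qquad
pO_{2,\mathrm{crit}}(T, B) = B^{n}\, A_o \exp\!\Big(\frac{E_o}{k_B T}\Big).$$

Supply is the ambient oxygen partial pressure (kPa). Demand is the critical
partial pressure below which a standard metabolic rate can no longer be met
and the fish oxyconforms. $T$ is absolute temperature, $B$ body mass (kg),
$n$ a mass scaling exponent, $k_B$ the Boltzmann constant in eV K$^{-1}$, and
$(A_o, E_o)$ come from an ordinary least-squares regression of
$\ln(pO_{2,\mathrm{crit}}/B^n)$ on the Arrhenius coordinate $x = 1/(k_B T)$:
the slope is $E_o$ and the exponentiated intercept is $A_o$.

A note on parameterisation. The index is sometimes written with the demand
term as $\exp(-E_o/k_BT)$ in a denominator and $A_o$ as a leading constant
multiplying $B^n\,pO_2$. Under that reading, coefficient values such as
$A_o \approx 1.6\times10^{9}$ with $E_o \approx -0.49$ above 12 °C produce
physically absurd demand (tens of thousands of kPa) and $\phi$ values near
85 under ordinary shelf conditions. We therefore adopt the interpretation in
which the regression intercept *is* $\ln A_o$ and the slope *is* $E_o$ on
the demand side, i.e. $pO_{2,\mathrm{crit}} = B^n A_o e^{E_o x}$. With the
reference coefficients this yields demand of 3.6–6.5 kPa across 8–24 °C,
branch agreement at 12 °C within 0.0005 kPa, and habitat $\phi$ in the
plausible 1–5 range — three independent consistency checks that the adopted
reading is the operative one. This convention is used everywhere in the
package and is what `phi_params()` stores.

### Bidirectional hypoxia tolerance and the piecewise fit

Hypoxia tolerance need not degrade monotonically with cooling: demand can
rise again below an optimum because oxygen *supply capacity* falls in cold,
viscous water. The package models this with two Arrhenius branches joined at
a breakpoint temperature (default 12 °C, settable but not searched for):
temperatures strictly below the breakpoint use the lower branch, the
breakpoint itself and everything above use the upper branch, and trials run
exactly at the breakpoint inform *both* branch regressions. A branch needs
at least two distinct test temperatures; two groups (the usual design below
the optimum, e.g. 8 and 12 °C) identify the branch line exactly, and the
constructor warns when the two branches disagree at the breakpoint by more
than 5%.

### Mass scaling

The exponent $n$ is fitted by alternation: (i) provisional per-branch
Arrhenius fits at the current $n$ (starting at 0); (ii) each pO₂crit is
divided by its branch's *full* fitted value $A_o e^{E_o x}$ — the intercept
must be included because the two branches sit at wildly different $A_o$
scales; (iii) a log–log least-squares fit of the temperature-standardised
pO₂crit against mass gives the next $n$. Iteration stops when
$|\Delta n| < 10^{-4}$ (20-iteration cap). On noiseless synthetic cohorts
the scheme converges in ~5 iterations and recovers the planted $n$ to
4 decimal places; whether the original analyses iterated at all is not
documented, but a single pass leaves an $O(n \cdot \mathrm{cov})$ bias that
the alternation removes.

## Respirometry estimators

* **SMR** is the 0.2 quantile (linear interpolation between order
  statistics, `stats::quantile` type 7; both quantile level and type are
  arguments) of all pre-chase metabolic-rate measurements. At least 10
  routine measurements are required.
* **MMR** is the maximum post-chase rate.
* **O2crit** intersects the SMR line with an OLS regression through up to
  `max_points` (default 15) of the *lowest-saturation* measurements whose
  rate fell below SMR — low-saturation points are preferred because the
  contamination risk is near-SMR points smuggled in from *above* the true
  critical level, which bias the intersection upward. The estimate is
  converted from % air saturation to kPa at the trial's own test
  temperature.

An automated check replaces the visual inspection of suspect fits. The
4-point refit (one more point than a regression minimally needs) is applied
when the full fit shows any of: a slope not significantly greater than zero
(one-sided t, $\alpha = 0.05$); $R^2 < 0.5$; or an intercept significantly
greater than zero. The third trigger operationalises the defining property
of oxyconformity — rates decline *in proportion to* saturation, i.e. through
the origin — so a clearly positive intercept indicates plateau points in the
regression. Because the refit exists to correct overestimates, it is adopted
only when it is valid and *lowers* the estimate; otherwise the full fit
stands. A per-trial manual override (`force_adjust`) is available. On
noiseless piecewise-linear traces the estimator returns the analytic
intersection to machine precision.

## Unit conversions

All conversions are pinned, self-consistent published formulations, chosen
because no worked conversion example exists to match against:

* % air saturation ↔ kPa: $pO_2 = (s/100)\,\chi_{O_2}(P_b - p_w(T))$ with
  $\chi_{O_2} = 0.20946$, barometric pressure defaulting to 101.325 kPa
  (lab pressure unrecorded) and Buck (1981) vapour pressure, with the
  Green & Carritt seawater depression when salinity is supplied.
* concentration → kPa: Garcia & Gordon (1992) solubility (Benson–Krause
  coefficients, ml l⁻¹ × 44.6596 → mmol m⁻³), linear in concentration, with
  a Henry's-law hydrostatic correction $\exp(V_m P / RT)$,
  $V_m = 32\ \mathrm{cm^3\,mol^{-1}}$ (~1.3% at 100 dbar). Whether a
  hydrostatic term belongs in the solubility itself or only in the unit
  transform is genuinely ambiguous; we document this choice rather than
  assert it.
* depth → pressure: Saunders (1981) with latitude-dependent gravity.

## Gridded projection

Stacks are (time, lat, lon) arrays with NA as mask. Coastal gaps are filled
iteratively by the mean of valid 8-neighbours (the neighbourhood size is our
reading of "surrounding cells"); the fill is idempotent and never touches
valid cells. Bilinear refinement doubles resolution using cell-centre
interpolation clamped at the grid edge, so constants and linear ramps are
reproduced exactly. ϕ is projected at a reference mass of 1 kg: the $B^n$
factor is spatially constant and a monotone classifier is invariant to it,
so no projection mass needs to be asserted. Min/mean/max aggregates use all
monthly slices of the requested period (60 months for a 5-year block): the
"minimum monthly" layer is the minimum over every month of the period.
Projection order matters — inputs are refined first, then ϕ is computed —
because ϕ is nonlinear in its inputs; the pipeline follows that order.

## Distribution modelling

Occurrence points collapse to unique grid cells via half-open cell intervals
(lower edge inclusive, so boundary points land in exactly one cell).
Pseudo-absences are sampled uniformly without replacement from domain cells
excluding presences and their 8-neighbours (queen adjacency, our reading of
"adjacent"). Each of the $k = 10$ ensemble members gets its own
pseudo-absence draw (balanced to the presence count), its own stratified
80/20 split, and a per-model seed derived from the master seed. Forests use
500 trees, $\lfloor\sqrt p\rfloor$ candidate predictors per split, unlimited
depth — all configurable. Class votes are thresholded at 0.5 deterministically
(`randomForest`'s own tie-breaking is random, which would make accuracies
and agreement maps depend on RNG state and model order). Importance is the
mean decrease in *test-set* accuracy under predictor permutation (whether
the original used out-of-bag or test data is unstated; ours is labelled).

### Feature contributions and thresholds

For each tree, a prediction's path is walked from the root; at every split
on predictor $f$, the change in local presence probability (child minus
parent) is credited to $f$. Node probabilities are presence fractions of the
model's own training rows routed down the tree; empty nodes inherit their
parent's value. Averaged over trees the decomposition is exactly additive —
bias (root probability) plus contributions equals the forest's predicted
presence probability (tree-averaged leaf fraction) — which the tests check
to $10^{-10}$ per row.

ϕ_crit pools training-row min-ϕ contributions from all $k$ models, binarises
their sign (positive → 1), and fits a maximum-likelihood logistic regression
of the binary outcome on min ϕ; ϕ_crit is the 0.5 crossing $-\beta_0/\beta_1$
with a delta-method Wald interval. Clean synthetic data usually separates
completely; the documented fallback is the midpoint of the empirical
transition, flagged in the result. Depth thresholds average pooled depth
contributions in 2 m bins and interpolate the zero crossings bracketing the
positive region around the global-maximum bin; a missing crossing is an open
window, reported as NA with a message. Agreement maps count models voting
presence, scaled to 0–100, and future projections apply the
contemporarily-trained ensemble to future layers.

## The synthetic world

The generators plant a known truth and emulate the *statistical structure*
the estimators assume — not real coastal oceanography.

* **Respirometry traces**: a routine phase (60 cycles of 20 min) whose
  rates are SMR × (1 + |half-normal|) × (1 + Gaussian) — activity noise is
  one-sided upward because SMR is by definition a lower quantile; a
  post-chase phase decaying exponentially from MMR; and a progressive
  hypoxia phase at 5-min cadence in which saturation falls at a constant
  per-cycle rate while the fish regulates and proportionally to saturation
  once it conforms (the fish itself depletes a closed respirometer, so
  depletion tracks metabolic rate), ending ~16 cycles into conformity as
  stress signs appear. The per-cycle depletion scales with SMR(T)
  (0.68–2.5% saturation per cycle across 8–24 °C). Measurement noise is
  multiplicative Gaussian (default 5%).
* **Ocean grids**: bottom temperature ramps monotonically west (8 °C) to
  east (25 °C); relative oxygen saturation sits at 0.35 in a western
  upwelling band and reaches 1.0 at 45% of the extent, with concentration =
  saturation × solubility(T, S), so the west is cool *and* hypoxic while
  high-ϕ habitat is cool-but-saturated mid-shelf — min-ϕ spans ~0.9–3.8 and
  mean-ϕ ~1.2–4.6 across the default domain. A sinusoidal seasonal cycle
  (February peak; oxygen in antiphase) and a static seeded texture field are
  superposed; the future block adds warming (+2.5 °C) and deoxygenation
  (−0.08 saturation) strictly additively, with identical texture, so
  future-minus-contemporary differences equal the trends exactly. Depth
  ramps 2–98 m with latitude. Default treatments (five temperatures ×
  8 fish, masses 0.32–1.55 kg) and the grid (40 × 40 cells at 0.25°,
  60 months per period) match the scale of the study design the package
  targets.
* **Occurrences**: presences are uniform draws (with replacement, jittered
  within the cell to exercise deduplication) from cells with minimum
  monthly ϕ ≥ the planted ϕ_crit and depth inside the planted window; a
  label-noise fraction is re-drawn from unsuitable cells. Sampling effort
  and detectability are assumed uniform over suitable habitat.

What passing recovery tests therefore show is that the estimators are
consistent under the assumed error structure — multiplicative measurement
noise, exact piecewise-Arrhenius truth, threshold-determined occupancy.
They cannot show robustness to acclimation effects, behavioural O₂crit
variation, spatially biased sampling effort, or ocean-model bias, none of
which the generators emulate.

## Numerical choices and test design

* Boltzmann constant 8.617333×10⁻⁵ eV K⁻¹; K = °C + 273.15.
* Quantile type 7 for SMR (the interpolation default in scientific
  computing); configurable.
* Logistic separation fallback: midpoint between the largest min-ϕ with
  negative contribution and the smallest with positive.
* Vote threshold exactly 0.5, ties to absence.
* Parameter files round-trip through plain-text DCF at 17 significant
  digits; grid stacks through long-format CSV (one row per cell-month) —
  a deliberately dependency-free exchange format with the same
  (time, lat, lon) semantics as NetCDF layers.
* Test problem sizes: unit tests run on 20×20 toy worlds with k = 5–10
  forests of 60–100 trees; the end-to-end recovery checks use the full
  default world (40×40 cells, 60 months, ≥150 presence cells, k = 10 × 500
  trees), which completes in seconds per run.

### A note on intercept recovery tolerances

For a branch fitted from data spanning a narrow Arrhenius range centred at
$\bar x$, OLS pivots the line about the data centroid, so the intercept
error is deterministically $\bar x$ times the slope error — with
$\bar x \approx 41$ eV⁻¹ for the 8–12 °C branch, a slope error of just
0.02 eV (well inside a 0.05 eV tolerance) already implies a ln A_o error of
~0.85. Simulation across trace designs puts the per-trial pO₂crit error
floor near 2.4% under 5% measurement noise with the 15-point OLS
intersection, giving a lower-branch ln A_o median error of ~0.9 at the
study's sample sizes. Intercept tolerances for that branch therefore cannot
be meaningfully tighter than ~1.0 unless slope tolerances are tightened
four-fold; the upper branch (four temperatures, 32 trials) recovers
ln A_o to ~0.2–0.3. The test suite asserts both branches at the tighter
bound and the lower-branch expectation documents this analysis where it
fails.

## Known limitations

* The breakpoint is fixed, not estimated; no hierarchical/Bayesian variant.
* No background-respiration correction or within-cycle slope fitting; the
  input is already per-cycle mass-specific rate.
* Regridding is factor-n bilinear refinement only; no reprojection or
  shoreline geometry.
* The SDM offers only random forests with random 80/20 splits — no spatial
  cross-validation, MaxEnt/GLM/BRT alternatives, or abundance modelling.
* ϕ aggregation at monthly resolution cannot resolve sub-monthly hypoxia
  exposure.
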