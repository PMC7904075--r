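# phimap

Calibrate the **metabolic index** of a marine ectotherm and map the aerobic
habitat it defines.

The metabolic index is the ratio of oxygen supply to resting oxygen demand,

&nbsp;&nbsp;&nbsp;&nbsp; ϕ = pO₂ / pO₂crit(T, B), &nbsp;&nbsp;
pO₂crit(T, B) = Bⁿ · A_o · exp( E_o / (k_B·T) ),

where pO₂ (kPa) is the ambient oxygen partial pressure, pO₂crit the minimum
partial pressure that sustains a standard metabolic rate at absolute
temperature T for a fish of mass B (kg), n the mass scaling exponent, k_B the
Boltzmann constant (8.617333×10⁻⁵ eV·K⁻¹), and (A_o, E_o) the intercept scale
and slope of the Arrhenius regression of mass-standardised ln(pO₂crit) on
1/(k_B·T). ϕ = 1 means a habitat barely sustains resting metabolism; species
typically persist only where ϕ stays above a species-specific critical value
ϕ_crit, and hypoxia tolerance can be *bidirectional*: pO₂crit rises both
above and below an optimal temperature, captured here by a piecewise fit with
branch-specific (A_o, E_o) on either side of a breakpoint (default 12 °C).

The package covers the full analysis chain:

1. **Respirometry** — estimate SMR (bottom-20% quantile of routine
   measurements), MMR (post-chase maximum) and O2crit / pO₂crit (intersection
   of the SMR line with the OLS fit through sub-SMR rates during progressive
   hypoxia, with an automated overestimate check) from per-individual traces.
2. **Calibration** — `phi_calibrate()` fits the mass exponent by alternating
   temperature/mass standardisation and the piecewise Arrhenius demand model;
   returns a classed `phi_fit` with `print`, `summary`, `coef`, `predict`
   and `plot` methods. Group effects (capture area, sex stage) are testable
   with `test_group_effects()`.
3. **Gridded layers** — convert oxygen concentration to partial pressure
   (Garcia–Gordon solubility, Saunders depth–pressure, Buck vapour pressure),
   fill coastal gaps, refine grids bilinearly, project monthly ϕ / aerobic
   scope layers and aggregate min/mean/max over a period.
4. **Distribution modelling** — presence/pseudo-absence random-forest
   ensembles (k models, each with fresh pseudo-absences and an 80/20 split),
   tree-path feature contributions (exactly additive per prediction),
   logistic extraction of ϕ_crit and zero-crossing extraction of depth
   thresholds, and 0–100 ensemble agreement maps.
5. **Synthetic data** — planted-truth generators for respirometry cohorts,
   seasonal ocean grids (warm eastern edge, cool hypoxic upwelling edge) and
   occurrence sets, so every stage is verifiable by parameter recovery.

## Worked example

Simulate a study cohort from a planted truth, calibrate, and recover the
planted habitat thresholds end to end:

```r
library(phimap)

truth  <- planted_truth(seed = 42)          # phi_crit = 3, depth window 13-75 m
cfg    <- synthetic_config()                # 5 treatments x 8 fish, 40x40 grid
cohort <- generate_respirometry_cohort(cfg, truth)
cal    <- process_trials(cohort$trials)     # per-trial SMR + pO2crit (kPa)
fit    <- phi_calibrate(cal)
fit
#> Calibrated metabolic index
#> Metabolic-index parameters (pO2crit = B^n A_o exp(E_o/(kB T)))
#>   breakpoint: 12 degC; mass exponent n = 0.1779
#>   upper branch (T >= 12): A_o = 1.93347e+09, E_o = -0.4935 eV
#>   lower branch (T <  12): A_o = 2.67645e-18, E_o = 1.0263 eV
#>   mass exponent fitted in 5 iteration(s)
#>   40 trials, 5 distinct temperatures

env <- generate_environment(cfg, truth)
occ <- generate_occurrences(env, truth, cfg)
res <- sdm_pipeline(env, fit, occ$points, k = 10, seed = 1)
res$phi_crit
#> phi_crit = 2.945 (interval 2.939-2.950)
res$depth_thresholds[c("lower", "upper")]
#> $lower: 12.1   $upper: 75.5
```

The planted slope E_o = −0.4885 eV (upper branch) is recovered as −0.494 and
the planted n = 0.17 as 0.178 from 40 noisy trials; pushing the *fitted*
index through the ocean grids and the 10-forest ensemble returns the planted
ϕ_crit = 3 as 2.945 and the 13–75 m depth window as 12.1–75.5 m. With the
reference parameter set (`phi_params(1.55951e9, -0.4885, 5.109275e-18, 1.01,
n = 0.17)`), `po2crit_predict()` gives 4.77 kPa at 16 °C and 6.50 kPa at
8 °C — the bidirectional tolerance curve — and `phi()` gives 3.77 at
16 °C / 18 kPa.

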