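---
title: "Models and methods behind phbdeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phbdeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phbdeg)
```

# The scientific problem

Bacterial polyesters such as
poly(3-hydroxybutyrate-*co*-3-hydroxyhexanoate) (PHBHHx) biodegrade in
soil through a multistep process: microbial colonization of the polymer
surface (dominated by filamentous organisms — fungi and actinomycetota —
on initially dry film surfaces), extracellular enzymatic hydrolysis of
the polyester backbone, and microbial assimilation of the hydrolysis
products. Incubation experiments track the residual polymer mass in soil
over time, at several constant temperatures and in several soils.
`phbdeg` implements the quantitative layer of such a study: kinetic
fitting, temperature analysis, NMR-based quantification, and
colonization metrics, plus a synthetic-data generator that emulates the
study design so every stage can be validated against known ground truth.

# Shoulder-log-linear kinetics

Residual mass is modelled as

$$ m(t) = m_0 \, e^{-kt} \, e^{kL} \; / \; \bigl(1 + (e^{kL} - 1)\,e^{-kt}\bigr) $$

with $m_0$ the initially added mass, $k$ (d$^{-1}$) the
pseudo-first-order mass-loss rate constant and $L$ (d) the duration of
the initial shoulder, interpreted as the lag needed for microbial
colonization of the polymer surface. The model equals $m_0$ exactly at
$t = 0$, is monotone non-increasing for $k, L \ge 0$, approaches slope
$-k$ on the log scale for $t \gg L$, and collapses to ordinary
exponential decay when $L = 0$. A useful closed form: at $t = L$ the
residual mass is $m_0 / (2 - e^{-kL})$.

## Fitting choices

- **$m_0$ is fixed at 100 %**, the normalized added mass, not fitted.
  Residual masses are expressed as percent of the mass added to each
  vial, so the intercept is known by construction; fitting it would
  spend a degree of freedom on a quantity the design already pins down.
- **Fits use per-time-point replicate means** with unweighted residuals.
  Replicate vials sacrificed at one sampling time are subsamples of the
  same condition, not independent trajectories; averaging avoids
  pseudo-replication. No weighting scheme is applied because the
  replicate scatter is roughly constant on the percent scale (the noise
  model below makes the same assumption).
- **Optimizer**: Levenberg–Marquardt (`minpack.lm::nls.lm`) with box
  bounds $k \in [0, 10]$ d$^{-1}$ and $L \in [0, \max t]$. Starting
  values: $k$ from an OLS slope of $\log(\text{mean})$ over the
  declining phase, $L$ from the latest time at which the mean is still
  $\ge 95\,\%$ of $m_0$ (else 0). Up to 10 deterministically jittered
  restarts are attempted on failure. Because the free-lag model nests
  the $L = 0$ model, the free fit is additionally restarted from the
  best lag-zero solution; LM descends monotonically on the RSS, so the
  reported free-lag RSS can never exceed the lag-zero RSS. Persistent
  non-convergence returns an explicit failure record with diagnostics
  rather than an error, so one pathological treatment cannot abort a
  multi-treatment run.
- **Uncertainties** come from the Gauss–Newton covariance
  $s^2 (J^\top J)^{-1}$, $s^2 = \mathrm{RSS}/(n - p)$, with two-sided
  Wald $t$ p-values on $n - p$ degrees of freedom. No multiple-testing
  correction is applied across treatments.
- **Degenerate series** (no measurable mass loss within the experiment)
  return a finite fit with $\hat{k}$ at or near zero. This mirrors slow
  soils at low temperature, where the lag phase may exceed the
  incubation or the rate is indistinguishable from lag-phase loss; the
  lag estimate is then unreliable and its p-value missing, which the
  model-selection rule treats as "lag not supported".

## Model selection and fit statistics

The lag term is retained only when its two-sided p-value is at or below
$\alpha = 0.05$ (a boundary p-value counts as significant); otherwise
the lag-zero fit is reported. Both variants' statistics travel with the
selected fit:

- $-2\log\mathcal{L} = n\,(\log(2\pi\,\mathrm{RSS}/n) + 1)$, the
  Gaussian likelihood at the MLE variance $\mathrm{RSS}/n$. The additive
  constants are included, so only *differences* between models fitted to
  the same series are meaningful.
- $\mathrm{AIC} = -2\log\mathcal{L} + 2p$ and
  $\mathrm{BIC} = -2\log\mathcal{L} + p\log n$, with $p$ the number of
  fitted parameters (2 free-lag, 1 lag-zero).
- $\chi^2 = \sum_i (\bar{y}_i - \hat{m}_i)^2 / (s_i^2 / n_i)$, the
  replicate-variance-weighted statistic, when every time point has a
  positive replicate standard deviation; otherwise the plain RSS with an
  explicit `chi_squared_is_rss` flag. This definition is declared, not
  inherited: it is the standard choice when per-point variances are
  estimated from replicates.

# Arrhenius analysis and Q10

Fitted rate constants across incubation temperatures are regressed as
$\ln k = -E_a/(RT) + \ln A$ by unweighted OLS on $1/T$ (kelvin;
conversion uses 273.15 exactly — the choice matters at below the 0.1 %
level). Unweighted regression is the deliberate default: per-point
standard errors of $k$ are carried as metadata but likely understate the
true uncertainty, and weighting by them would let single tight points
dominate. $E_a = -R \cdot \text{slope}$ with
$\mathrm{SE}(E_a) = R\cdot\mathrm{SE}(\text{slope})$ on $n-2$ degrees of
freedom; with exactly two points the SE is reported as missing rather
than zero. Temperature-window restriction is inclusive at both bounds,
supporting mid-range fits where the law shows curvature at the
temperature extremes (multistep biology is not a one-step reaction).

The Q10 coefficient is derived from $E_a$ over a stated range,
default 0–40 °C. Two conventions are implemented:

- **geometric-mean** (default):
  $Q_{10} = (k(T_\text{high})/k(T_\text{low}))^{10/(T_\text{high}-T_\text{low})}$,
  the average factor change over the whole span;
- **per-interval**: the arithmetic mean of
  $\exp\!\bigl(\tfrac{E_a}{R}(\tfrac1T - \tfrac1{T+10})\bigr)$ over
  consecutive 10 °C intervals.

Both agree within ~2 % for $E_a \le 130$ kJ mol$^{-1}$ over 0–40 °C
(e.g. 2.107 vs 2.110 at 53 kJ mol$^{-1}$). Literature values computed
with unstated averaging conventions can differ from either by a few
percent; neither convention is tuned to match any particular published
rounding.

# qNMR quantification

Quantification consumes a *peak table* — integrals with per-unit proton
counts — not spectra; acquisition, phasing, baseline correction and
deconvolution happen upstream in spectrometer software. Moles of each
repeat unit follow from the internal-standard ratio
$n_u = \frac{I_u/H_u}{I_\text{std}/H_\text{std}} \cdot
\frac{m_\text{std}}{M_\text{std}}$ with 1,4-dimethoxybenzene
(138.16 g mol$^{-1}$, 4 aromatic protons) as the default standard, and
residual mass is $n_\text{HB}\cdot 86.09 + n_\text{HH} \cdot 114.14$ mg.
Default diagnostic peaks are the 3-HB and 3-HH methyls (3 protons per
unit each) — well-separated resonances — but every proton count is a
user-overridable field, since assignment choices vary between
laboratories. The 3-HH comonomer content is the per-proton mole ratio
expressed in mole percent, invariant to uniform integral rescaling. A
quality flag is raised when the implied extract concentration falls
below 0.67 mg mL$^{-1}$ (given a tube volume), the level below which
deconvolution uncertainty grows sharply.

# Colonization metrics

The input is a label mask (intact 0 / hyphal skeleton 1 / dense colony
2 / hole 3); identifying those classes in raw SEM images is out of
scope. Hyphal length sums 8-connected skeleton steps — orthogonal pairs
count 1 px, diagonal pairs $\sqrt 2$ px — times the pixel size, divided
by imaged area. The metric is exact for axis-aligned and 45° runs and
deterministic, which is why it was chosen over perimeter- or
spline-based estimators. Colony and hole area fractions are pixel-count
ratios; the intact fraction is the remainder with skeleton pixels
counted as intact film (a hypha lies on film that is still present), so
fractions sum to one exactly.

# The synthetic-data generator

The generator emulates the study conditions: triplicate destructive
sampling, residual mass in percent of added mass, additive Gaussian
measurement noise with $\sigma = 2$ % (absolute) as the default study
condition, and a per-vial multiplicative extraction recovery of
$0.97 \pm 0.04$ mirroring spike-recovery measurements. Noise choices:

- **Additive Gaussian on the mass scale, truncated at zero.** Replicate
  error bars in such studies are roughly constant in percent terms
  across the degradation course, which an additive model reproduces;
  heteroscedastic or multiplicative alternatives are out of scope. The
  true assay-noise structure is not documented, so this is an
  assumption, stated as such.
- **Recovery drawn once per vial**, not per series, because each vial is
  extracted independently.
- **Seeds are mandatory** in every stochastic interface; there is no
  hidden global state, and equal arguments give identical output.

Rate-constant sets are generated directly from the Arrhenius law with
log-normal noise; NMR peak tables are built so that quantification
round-trips the generating mass and composition exactly at zero noise;
colonization masks place straight hyphal segments in disjoint bands
(plus colony/hole blocks on untouched area) so the ground-truth skeleton
length is known exactly.

What passing tests on these data do **not** show: robustness to
real-data features the generator omits — heteroscedastic or correlated
measurement error, incomplete extraction that varies with degradation
stage, non-first-order late-stage kinetics, overlapping NMR resonances,
and curved or branching hyphae whose length the step metric only
approximates.

# Problem sizes and numerical checks

The shipped analyses use sizes chosen to make the statistical behaviour
visible while keeping every run quick on a laptop: 12 time points
spanning the lag plus three e-foldings ($L + 3/k$), 3 replicates, 200
simulated studies per treatment for recovery statistics (50 in the
analysis driver). The recovery study reproduces $k$ with worst-case
median bias well under 1 % and detects true lags at 25–35 °C in 100 %
of runs at these settings. The independent oracle for the fitter is a
dense $(k, L)$ grid search with local refinement; the fit must match it
within one coarse grid step and never exceed its RSS.

Known limitations: absolute AIC/BIC values are convention-dependent
(constants included) and only comparable within a series; the lag
estimate is weakly identified when $L$ is comparable to the experiment
length or when $k$ is very small (flagged rather than hidden); and the
Arrhenius law is used as a descriptive summary — no curvature models are
fitted even where the data hint at them.
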