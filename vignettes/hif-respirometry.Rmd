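---
title: "Methods: heat increment of feeding from breath-by-breath respirometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat increment of feeding from breath-by-breath respirometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the assumptions, the defaults and the
numerical choices behind `hifresp`. Code chunks are illustrative and not
evaluated when the vignette is built.

## 1. The measurement model

A dolphin breathes into a flow-through dome. Two channels are recorded on a
shared uniform time grid: airflow (l s⁻¹, expiration positive) and expired
gas fractions (O2, CO2). Oxygen uptake for one breath is the flow-weighted
O2 deficit integrated over the expiratory window:

V̇O2(breath) = ∫ max(flow, 0) · (F_I,O2 − F_E,O2) dt,

with inspired fractions fixed at atmospheric values (F_I,O2 = 0.2095,
F_I,CO2 = 0.0004). Trial-level V̇O2 is the sum over breaths divided by trial
duration, so pauses between breaths dilute the rate exactly as they do
physiologically. Integration windows are half-open `[t_start, t_end)` on the
sample grid and never overlap.

Before integration the raw channels pass through three corrections, in
order:

1. **Flow calibration.** A syringe of known volume (default 7 l) is pumped
   at several speeds; the gain is chosen so the mean absolute stroke
   integral equals the known volume. Stroke windows are found on a
   low-pass-smoothed copy of the signal (10 Hz Butterworth, zero-phase
   `filtfilt`) so sensor noise can neither bridge the push/pull gap nor
   split a stroke; integration always uses the raw samples.
2. **Phase alignment.** Gas is sampled through a tube, arriving a transport
   delay late (default 0.43 s). The default removes the configured delay
   (fixed tubing geometry); alternatively the delay is estimated by
   cross-correlating the CO2 excursion with positive flow (`method =
   "xcorr"`). The fixed default was chosen because the cross-correlation
   estimate is skewed by the analyzer lag itself (by roughly a tenth of a
   second at the default settings).
3. **Response-time deconvolution.** The analyzers blur the true fractions
   with a first-order lag, time constant τ = t90 / ln 10 (t90: 67 ms for O2,
   94 ms for CO2). The inverse filter is x(t) = y(t) + τ·dy/dt with the
   derivative taken by central differences; because differentiation
   amplifies high-frequency noise, the result is regularized by a 4th-order
   10-Hz Butterworth low-pass (zero-phase). Correction is refused when
   τ < 2·dt ("under-resolved"): the discrete derivative cannot represent
   the inverse filter at such sampling.

Volumes are reported at STPD using
((P_b − P_H2O) / 760) · (273.15 / (273.15 + T)), with water vapour pressure
from the Arden Buck equation; expired gas is treated as saturated at body
temperature (37 °C), giving a factor of 0.826 at 760 mmHg.

## 2. The energetics accounting

* Kleiber allometry: predicted BMR = 0.0093 · M^0.75 l O2 min⁻¹ (M in kg);
  the Kleiber ratio is measured/predicted.
* A fasted measurement counts as BMR for adults and RMR for juveniles
  (growth violates the basal criteria); `classify_measurement()` encodes
  this.
* Excess postprandial volume over a window of length T:
  AUC − BMR·T. Energy equivalent 4.8 kcal per litre O2.
* HIF as %GEI: 100 · (excess volume · 4.8) / meal energy.
* Daily digestive cost: excess per meal ÷ meal fraction of daily intake,
  expressed against BMR·1440 min. The extended estimate adds a constant
  tail (default 0.8 l min⁻¹ from 133 to 170 min) for responses still
  elevated at trial end.
* Study-level statistics are unweighted means across animals (each animal
  one vote), because per-animal trial counts are unequal by design of the
  emulated study; trial-count-weighted means are available via
  `weighted = TRUE`.

## 3. The time-course model

`fit_timecourse()` fits, with `mgcv::gam`:

```{r}
vo2 ~ male01 + s(time, bs = "ts", k = 4) + s(intake, bs = "ts", k = 4) +
  s(age, bs = "ts", k = 4) + s(mass, bs = "ts", k = 4) +
  s(pool_temp, bs = "ts", k = 4) + te(time, intake, k = c(4, 4)) +
  s(animal_id, bs = "re") + s(day, bs = "re")
```

with `method = "ML"` and `select = TRUE`. Choices and reasons:

* **Shrinkage smooths (`bs = "ts"`) + `select = TRUE`**: nuisance covariates
  can be penalized entirely out of the model, which is what a true-null
  covariate (pool temperature in the generator) should experience.
* **`k = 4`**: five postprandial sampling times per trial cannot support
  more; larger `k` would be pure prior.
* **Random intercepts** for animal and day absorb between-animal physiology
  and day-to-day state; variance components are read off
  `mgcv::gam.vcomp`.
* **Sex as `male01`**: a numeric 0/1 indicator, so a population prediction
  can use a fractional value (e.g. 0.76 for a sample that is 76% male);
  under the additive sex effect this equals the same mixture of the two
  sex-specific curves (a property tested exactly).
* Terms whose covariate is constant in the data at hand (or a single-level
  grouping factor) are dropped with a warning rather than passed to mgcv,
  which would error.

**Population prediction is marginal over the sample.** The population curve
averages per-animal predictions (one covariate row per animal; random-effect
columns zeroed both via `exclude` and explicitly in the lp-matrix). The
plug-in alternative — evaluating at the mean covariate vector — was
implemented first and abandoned: with eight animals, `te(time, intake)` is
identified only near observed intakes, and at the unobserved mean intake the
tensor interpolant contributed arbitrary offsets (errors up to ±40 l of AUC
on some seeds; within ~3 l after marginalization). `profile =
list(male01 = 1)` pins a covariate instead of marginalizing it.

**What the AUC interval estimates.** Uncertainty comes from posterior draws
of the coefficients (Gaussian approximation by default;
`method = "mh"` for mgcv's Metropolis–Hastings sampler). With n = 8 animals
the marginal curve estimates the *realized sample's* mean curve, not the
superpopulation curve: the sample mean of the animal random effects (SD
0.13/√8 ≈ 0.046 l min⁻¹, i.e. ~6 l of AUC) is absorbed into the fit and is
invisible to the interval. Intervals are therefore calibrated against the
realized-sample truth and undercover the superpopulation truth; with so few
animals this is a property of the design, not of the estimator.

AUC uses the trapezoidal rule on a 1-min grid: exact for piecewise-linear
curves, and within 0.1% under grid halving for fitted curves (both tested).
Integration, not summation, so the window `[0, 133]` is respected exactly.

## 4. The synthetic generator

`make_study_dataset()` emulates the study design: 8 animals × 6 trials ×
5 sampling times (0, 30, 60, 90, 120 min after feeding).

| parameter | default | unit | rationale |
|---|---|---|---|
| `baseline_vo2` | 0.73 | l O2 min⁻¹ | study-mean BMR |
| `peak_fraction` | 0.36 | — | mean maximal postprandial rise |
| `peak_time` | 60 | min | observed peak timing |
| `return_time` | 170 | min | response subsided by ~170 min |
| `animal_sd` | 0.13 | l O2 min⁻¹ | between-animal spread of fasted V̇O2 |
| `day_sd` | 0.087 | l O2 min⁻¹ | day-to-day spread |
| `residual_sd` | 0.20 | l O2 min⁻¹ | within-trial residual |
| `tidal_volume_mean/sd` | 3.7 / 1.3 | l | reported tidal volumes |
| `breath_rate_mean/sd` | 2.8 / 1.3 | min⁻¹ | reported breathing rates |
| `rer_mean` | 0.81 | — | postabsorptive RER |
| `t90_o2` / `t90_co2` | 0.067 / 0.094 | s | analyzer response times |
| `transport_delay` | 0.43 | s | gas line transit |
| `sample_rate` | 200 | Hz | resolves τ ≈ 29 ms comfortably |

The postprandial curve is a raised-cosine kernel: sin² rise from baseline to
the peak at `peak_time`, cos² fall back by `return_time`, flat outside. It
is continuous, unimodal, hits baseline/peak/return exactly (tested), and has
a closed-form integral (`hif_true_auc()`), so AUC oracles are analytic. The
kernel is deliberately *flat-topped* (within 5% of peak over roughly 51–76
min), which means the argmax of a fitted curve is intrinsically unstable
between replicates even when the fit is good; recovery checks therefore
aggregate peak estimates across 20 seeded replicates rather than demanding
each one land within the band.

Breath trains place half-sine expiratory lobes at the mean breath rate and
choose a constant expired-O2 deficit such that trapezoidal integration of
the sampled signals reproduces the target V̇O2 *exactly* — the generator's
ground truth is defined on the same grid and quadrature as the analysis, so
round-trip error isolates the processing chain. Instrument degradation
applies the first-order lag (exact recursive filter), an integer-sample
transport delay, and seeded Gaussian noise.

Per-animal randomness uses derived seed streams (`seed + 7919·i`), so adding
animals never perturbs existing animals' data (tested bit-for-bit).

What the generator does **not** emulate: RER drift during digestion, breath
volume/timing correlation with metabolic state, inter-breath apneas of the
kind free-swimming animals show, analyzer drift or calibration decay within
a session, and water-vapour dynamics in the dome (signals are generated as
dry STPD-equivalent fractions; `conditions` in `process_trial()` applies
STPD to real recordings).

## 5. Numerical choices worth knowing

* The lag inversion uses explicit central differences, not a generic
  gradient routine, and is regularized (Section 1). A blurred 0.05 step is
  recovered to <0.1% of plateau; a 5-Hz sinusoid's amplitude to within 2%.
* `mgcv::gam` cannot fit exactly-zero residual variance (degenerate ML), so
  "noise-free" model tests use `residual_sd = 0.02`.
* The breath count per trial uses `floor(x + 1e-9)`: the designed
  5 min × 2.8 min⁻¹ = 14 breaths sits exactly on a floating-point floor
  boundary.
* Config provenance hashes use a small 32-bit polynomial hash whose
  arithmetic stays below 2^53 (exact in doubles); it identifies configs in
  file headers and is not cryptographic.
* All tables and traces are delimited text (UTF-8, `#` comment headers
  carrying seed/config hash/units); respirometry has no entrenched binary
  standard and text keeps every artefact diffable.

## 6. Decisions on open questions

* **Expiration-only integration**: inspired air is atmospheric in a
  flow-through dome, so inspiration carries no uptake information; negative
  flow is clipped in the integrand rather than modeled.
* **Fixed-delay alignment by default**, cross-correlation as an option
  (Section 1).
* **Unweighted study means** across animals (Section 2).
* **Meal-fraction rounding**: the emulated study's printed worked example is
  internally inconsistent at the rounding level — its daily-cost chain
  (85.7 l day⁻¹, 8.2%) implies the unrounded meal fraction 19.6/85.7 ≈
  0.229, while its extended chain (128.7 l day⁻¹, 12.2%) uses the rounded
  0.23. The package exposes `meal_fraction` as an explicit argument and the
  tests reproduce each printed intermediate with the fraction that printed
  chain used.
* **Day-matched peak rises**: each day's postprandial peak is compared to
  that day's fasted measurement (default), isolating the feeding response
  from day effects; `day_matched = FALSE` compares to the animal's overall
  BMR.

## 7. Limitations

* Eight animals is few: animal-level covariate smooths (mass, age, intake)
  are weakly identified and partially confounded with the animal random
  intercept; treat their term tests with caution.
* The AUC interval is calibrated for the realized sample, not the species
  (Section 3).
* The generator's ground-truth curve is shared across animals by default
  (`shared_curve = TRUE`); real animals differ in response shape, not just
  level.
* STPD correction assumes saturated 37 °C expirate; airway cooling in cold
  air would bias volumes slightly high.
* The CLI is a thin wrapper for the packaged pipeline, not an acquisition
  or monitoring tool.
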