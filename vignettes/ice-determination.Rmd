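---
title: "Determining ion collection efficiency at ultra-high dose per pulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining ion collection efficiency at ultra-high dose per pulse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uhdrICE)
```

## The problem

In FLASH-regime radiotherapy research, electron linacs deliver microsecond
pulses carrying up to tens of gray each. An air-filled ionization chamber
exposed to such a pulse liberates so much charge that a substantial fraction
recombines before reaching the electrodes, and the chamber under-reads. The
ion collection efficiency

$$\mathrm{ICE}(\mathrm{DPP}) = \frac{Q}{Q_\mathrm{sat}(\mathrm{DPP})}$$

is the ratio of collected charge to the saturation charge — what would be
collected with no recombination (and, in this workflow, no separate polarity
correction: the two effects are deliberately left entangled, so
$\mathrm{ICE} = 1/(k_s\,k_\mathrm{pol})$). Micro chambers, with active
volumes of a few mm³, recombine less and are therefore candidates for online
FLASH dosimetry, but their efficiency still has to be characterized as a
function of the dose per pulse (DPP) before use.

Because no dose-rate-independent primary standard exists at these dose
rates, the reference dose comes from radiochromic film, which responds
independently of dose rate. The package implements the complete film-anchored
determination:

1. **Film calibration** (`fit_film_calibration`, `od_to_dose`): a degree-5
   polynomial of dose versus net optical density, fitted on duplicate films
   at ten dose points over 0.1–30 Gy, with an explicit uncertainty budget.
2. **Chamber dose equation** (`k_tp`, `dose_from_charge`,
   `fit_calibration_coefficient`): the TRS-398-style product
   $D = M\,N\,k_{TP}k_h k_\mathrm{elec} k_\mathrm{pol} k_s$, with the
   non-essential factors defaulting to 1 and $k_s$ never applied here —
   saturation is handled by the ICE itself, applying both would
   double-correct.
3. **Beam-monitor correction** (`bct_correct`): each condition is measured
   with three shots; one carries the companion film. The two film-less shots
   are rescaled to the companion's beam output using the beam-current
   transformer (BCT) signal, reducing the shot-to-shot charge SD from about
   1.0% to about 0.4%.
4. **Saturation anchoring** (`fit_qsat`): at the largest source-to-surface
   distance (SSD, 2 m) the per-pulse charge stays below 20 pC and
   recombination is negligible; a through-origin line of charge versus DPP
   there defines $Q_\mathrm{sat}(\mathrm{DPP})$, and its reciprocal slope is
   the chamber's calibration coefficient in the pulsed beam.
5. **ICE points and model fit** (`compute_ice`, `fit_logistic`): each shot
   yields $\mathrm{ICE} = Q\,k_{TP}\,N/\mathrm{DPP}$, with the DPP at the
   chamber transferred from the surface film dose through the depth-dose
   factor $k_F$; per pulse duration the points are fitted with the empirical
   logistic recombination model
   $$\mathrm{ICE}(\mathrm{DPP}) = \left(1 +
   (\mathrm{DPP}/\gamma)^{\alpha}\right)^{-\beta},\qquad
   \alpha,\beta,\gamma > 0 .$$
6. **Uncertainty propagation** (`mc_slope_sd`, `mc_curve_envelope`):
   GUM-style Monte Carlo — 2-D Gaussian clouds around the measured points,
   refitting per draw — for the saturation slope and for a pointwise
   envelope around the fitted curve.

The logistic form is pinned at ICE = 1 for DPP → 0, decreases strictly, and
its parameters have no individual physical meaning; only the curve does. One
sign convention matters: the exponent is $-\beta$ with $\beta > 0$. Only this
orientation yields a decreasing efficiency and reproduces the reference
values bundled in `default_ice_models()` (for the 3-mm³ micro chamber:
$\alpha=0.76, \beta=0.61, \gamma=5.12$ Gy at 1 µs and
$\alpha=0.97, \beta=0.35, \gamma=3.28$ Gy at 3 µs, giving ≥ 85% efficiency
at 1 Gy/pulse and ≥ 55% at 10 Gy/pulse).

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `shot_sd` | 0.010 | relative | per-pulse beam output SD |
| `residual_sd` | 0.004 | relative | output SD remaining after BCT correction |
| `film_interfilm_sd` | 0.005 | relative | duplicate-film spread at calibration |
| `ref_dose_sd` | 0.015 | relative | reference-chamber dose at calibration |
| `film_roi_sd` | 0.03 | relative | film inhomogeneity in the 2-mm ROI |
| `channel_dev_high` | 0.05 | relative | inter-channel deviation above 15 Gy |
| `kf_sd` | 0.025 | relative | duplicate $k_F$ spread |
| `charge_threshold_nc` | 0.020 | nC | saturation-anchor acceptance (20 pC) |
| `breakpoint_gy` | 15 | Gy | low/high film-dose budget switch |
| coverage $k$ | 2 | — | expansion of the ICE budget to 5.8% |

The budgets combine quadratically where components are independent
(0.5, 1.5 and 3 → 3.4% film dose below 15 Gy; with the 5% channel deviation →
6%; with the 2.5% $k_F$ → 4.2% and 6.5% on DPP) and arithmetically —
conservatively — for the ICE itself (0.4% charge repeatability + 2.5%
saturation slope → 2.9%, quoted expanded as 5.8% at $k=2$). The breakpoint
convention is half-open: a computed dose of exactly 15 Gy uses the low
budget.

## The synthetic generator

`ground_truth()` + `generate_*()` emulate one full measurement campaign so
that every stage is testable without measured data:

* **Beam.** Pulse trains at 10 Hz. Each pulse's relative output is
  $o_p = (1+u_p)(1+v_p)$ with $u_p$ the component the BCT sees
  (SD $\sqrt{0.010^2-0.004^2}$) and $v_p$ the component it cannot
  (SD 0.004). Both are plain Gaussian relative factors: at ≤ 3% SD the
  distinction from lognormal is negligible. This variance split is what
  makes BCT correction reduce the observed SD from 1.0% to 0.4%, as the
  repeatability of the emulated beam line shows.
* **Chamber.** Per-pulse charge $o_p\,\mathrm{DPP}\,
  \mathrm{ICE}_\mathrm{true}(o_p \mathrm{DPP})/N$, with
  $\mathrm{ICE}_\mathrm{true}$ the configured logistic model for the pulse
  duration, summed over the shot and divided by the $k_{TP}$ of jittered
  ambient conditions (so the downstream correction has something to undo).
* **Film.** The ground-truth response is the inverse of an increasing odd
  quintic, $D(\mathrm{od}) = 1.8\,\mathrm{od} + 2\,\mathrm{od}^3 +
  9.8\,\mathrm{od}^5$ (netOD ≈ 0.055–1.2 over 0.1–30 Gy). Any smooth
  monotone saturating response would emulate the physics; this one is chosen
  because it lies exactly inside the degree-5 calibration family, so the
  zero-noise pipeline identity is exact rather than limited by
  polynomial-approximation error of an out-of-family curve.
* **Replica grid.** Four SSDs × ten grid-tension levels × both pulse
  durations, with log-spaced DPP per SSD (2 m: 0.01–0.05 Gy; 0.5 m:
  0.2–4 Gy; 0.3 m: 1–12 Gy; 0.2 m: 3–30 Gy) — the machine's actual
  tension-to-DPP mapping is not public, so a monotone mapping is configured,
  not hard-coded. Pulse counts follow `clamp(round(2/DPP), 1, 100)` to keep
  each film inside its calibrated range. The 2-m anchor block stops at
  0.05 Gy: the logistic never actually reaches 1, so anchors carry residual
  recombination, and capping them at 0.05 Gy keeps the resulting bias on the
  anchored coefficient below 1% (it is ≈ 1.6% if anchors extend to 0.1 Gy).
* **Seeding.** One integer master seed; each table draws from a derived
  substream, so the calibration set, session and $k_F$ table are
  independently bit-reproducible and the caller's RNG state is untouched.

What the generator does **not** emulate: scanner optics and lateral response
maps, film batch effects, spectral changes with SSD (only their net scalar
effect through $k_F$), correlated drifts between film and chamber response,
and polarity-vs-recombination entanglement. Passing tests therefore
demonstrate that the pipeline's algebra, statistics and uncertainty
propagation are correct under the stated noise structure — not that a real
beam line holds no further surprises.

## Numerical choices

* **Film fit.** Dose as a degree-5 polynomial of netOD, least squares with
  `1/dose²` weights by default. Film uncertainties are relative; over
  0.1–30 Gy an unweighted fit leaves the low-dose end unconstrained in
  absolute terms and the polynomial then oscillates below the lowest knots —
  with realistic noise roughly one calibration in eight fails the
  monotonicity check. Relative weighting removes that failure mode and
  changes nothing on noiseless data; `weighting = "none"` restores the plain
  fit. Monotonicity is verified on a 512-point grid of the fitted
  derivative; a non-monotone curve is an error, not a warning, because a
  non-invertible calibration silently corrupts every downstream dose.
  Extrapolation beyond the calibrated netOD range is refused outright.
* **Logistic fit.** Unweighted least squares on the ICE values (the points
  carry a common relative budget, and the fitted quantity is order 0.1–1
  across the range, so weighting changes little; the reference fits also
  quote plain R²). Multi-start over
  $\alpha \in \{0.5,1,2\}$, $\beta \in \{0.3,0.6,1\}$,
  $\gamma \in \{\mathrm{median(DPP)},1,5\}$ Gy with the lowest-SSR converged
  fit retained; ties broken by first occurrence. Requires ≥ 6 points over
  ≥ 2 decades of DPP, and errors explicitly when all ICE ≈ 1 ($\gamma$ is
  then unidentifiable). Monte-Carlo refits start from the base fit and fall
  back to the grid on failure; failed draws are dropped and counted, never
  imputed, with an error above a 10% failure rate.
* **ICE values above 1.** Retained and flagged, not clipped: with a 4–5%
  DPP uncertainty, plateau points scatter symmetrically around 1, and
  clipping would bias the low-DPP plateau downward. A warning fires above
  1.05, where noise alone becomes an implausible explanation.
* **Through-origin fits.** Both the linearity calibration and the
  saturation anchoring force the line through zero (no dose, no charge); the
  free-intercept fit is reported as a diagnostic only.

## Parameter identifiability

The logistic model is *sloppy*: $\beta$ and $\gamma$ trade off along a
likelihood ridge (at large DPP the curve behaves as
$(\mathrm{DPP}/\gamma)^{-\alpha\beta}$, so only the product $\alpha\beta$
and a compound scale are strongly determined). Two practical consequences,
both visible in `recovery_experiment()`:

* The fitted **curve** is stable — replicate experiments at the documented
  noise levels recover the generating curve pointwise and with high R² —
  while the individual parameter estimates wander along the ridge.
* The sampling distribution of $\hat\gamma$ (and $\hat\beta$) is
  heavy-tailed to the right; ridge excursions are genuine global minima of
  their noisy realizations, not optimizer failures. Means of recovered
  parameters over replicates are therefore biased upward even though the
  medians sit on the generating values; `summarize_recovery()` reports
  both. Any user comparing recovered parameters across chambers or pulse
  durations should compare curves (or medians), never means of
  $\hat\beta,\hat\gamma$.

The package reports what the estimator honestly produces; it does not trim,
clip or re-weight to force parameter means onto the generating values.

## Problem sizes

The bundled checks use the sizes the workflow itself prescribes: 10 dose
points × 2 films for calibration; 80 beam conditions × 3 shots per session;
100 replicate experiments of 30 log-spaced DPP points for parameter
recovery; 5000 Monte-Carlo draws for the slope SD and 1000 for the curve
envelope (tests use fewer draws where only a qualitative property is
checked). SD-convergence checks run at $n = 10^4$ with 3σ Monte-Carlo
bands.

## Known limitations

* The polarity factor is never decorrelated from recombination; the ICE
  deliberately absorbs both. Comparisons with setups that correct polarity
  separately must multiply it back.
* The anchored calibration coefficient inherits a sub-percent downward bias
  in the slope (upward in Gy/nC) from residual recombination at the anchor
  DPPs; it is a property of the anchoring method itself, consistent with the
  ~1% difference between a conventional-beam coefficient and a pulsed-beam
  anchored one.
* The uncertainty Monte Carlo assumes independent Gaussian relative errors
  per point and axis; correlated error models (film batch, beam drift) are
  out of scope.
* The film module handles a circular-ROI mean on a pixel array; full
  scanner-inhomogeneity maps and double-exposure protocols are not
  implemented.
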