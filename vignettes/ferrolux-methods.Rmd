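---
title: "Methods: chlorophyll-normalized fluorescence as an iron-limitation diagnostic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chlorophyll-normalized fluorescence as an iron-limitation diagnostic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferrolux)
```

## The diagnostic and its assumptions

Iron-limited phytoplankton fluoresce more per unit chlorophyll *a* than
nitrogen-limited ones: the photosynthetic membrane holds less Fe-rich
photosystem I and cytochrome *b₆f* relative to photosystem II, and
Fe-stress pigment–protein complexes accumulate with weak energetic
coupling to either reaction centre. Both effects raise the chlorophyll
fluorescence quantum yield, so the chlorophyll-normalized fluorescence
**F/Chl** — passive (sun-induced fluorescence line height over
chlorophyll) or active (flash-stimulated fluorescence over extracted
chlorophyll) — tracks the strength of iron limitation.

`ferrolux` assumes:

1. **Light saturation.** F/Chl depends on irradiance at low light but
   saturates above roughly 500 µmol photons m⁻² s⁻¹, where increasing
   excitation is compensated by non-photochemical quenching. Shipboard
   yields are therefore characterized by the saturating response
   $F/\mathrm{Chl} = a \tanh(b\,\mathrm{PAR}/a)$ and compared at midday
   (12:00–15:00 local solar time), and the early-afternoon satellite
   overpass is treated as fully light-saturated. This is why the
   normalization of the satellite nFLH product can be removed by a single
   geometric factor, $\cos(\mathrm{SZA})$.
2. **Linearity of chlorophyll and absorption within the mask.** Between
   0.1 and 0.4 mg Chl m⁻³ the chlorophyll–absorption relationship is
   effectively linear, so dividing FLH by chlorophyll (rather than by
   absorption) is adequate; outside that range the FLH detection limit and
   retrieval nonlinearity make the yield unreliable, hence the mask.
3. **Affine yield-to-limitation mapping.** Over the working range the
   yield maps linearly onto the model's Fe-limitation index, anchored at
   zero and at a saturation yield (defaults: 0.7 W m⁻² sr⁻¹ µm⁻¹
   [mg Chl m⁻³]⁻¹ → 0.78, the model's maximum limitation). Both anchors
   and the ceiling are configuration, never fitted.

## The comparison procedure

For a monthly regional record (default: the standard Niño3 box, 5° S–5° N,
150° W–90° W):

1. multiply nFLH by $\cos(\mathrm{SZA})$ at each pixel latitude for the
   composite mid-date (overpass local solar time 13.5 h by default);
2. mask chlorophyll outside $[0.1, 0.4]$ mg m⁻³ (bounds inclusive — the
   exclusion is stated with strict inequalities);
3. form the per-pixel yield FLH/Chl, then the cos(lat)-weighted regional
   mean per month (ratio first, then average);
4. subtract the record mean to form anomalies;
5. scale the yield series to limitation units and regress on the SST
   anomaly with the ranged major axis; do the same for the model's
   biomass-weighted $\mathrm{Fe_{Lim}} = 1 - \sum_i b_i L_i / \sum_i b_i$;
6. report the slope ratio (model/observed) with a ±10% scan of the upper
   scaling anchor.

The ranged major axis is used for both series because both axes carry
observational error and the two variables have different units: each
variable is ranged to $[0,1]$ by $(v - \min v)/(\max v - \min v)$, the
major-axis slope of the ranged cloud is computed from its covariance, and
the slope is back-transformed by the ratio of ranges. The line passes
through the bivariate means. $R^2$ is the squared Pearson correlation.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| FLH bands | 667, 678, 748 | nm | approximate MODIS-Aqua waveband centres |
| band extraction | linear interpolation | — | grid-independent; ±2 nm window mean available (`band_method = "window"`) |
| OC3 coefficients | operational MODIS set | — | vintage changes with reprocessing, so exposed as configuration |
| chlorophyll mask | 0.1–0.4, inclusive | mg m⁻³ | FLH detection limit below, absorption nonlinearity above |
| midday window | 12:00–15:00 | local solar h | brackets the early-afternoon overpass |
| overpass time | 13.5 | local solar h | nominal MODIS-Aqua equator crossing |
| region box | 5° S–5° N, 150° W–90° W | degrees | standard Niño3 definition |
| scaling anchors | 0 → 0, 0.7 → 0.78 | yield → limitation | saturation yield of the global composite; model's maximum limitation |
| rolling windows | 17 (Fv/Fm), 25 (yield) | min | time-based, matching shipboard practice |
| bootstrap | 1999 resamples, percentile | — | no closed-form CI for the ranged-MA slope |
| coverage threshold | ≥ 20% valid pixels/month | — | permissive; the mask rarely bites inside the box |

## What the synthetic generators emulate — and what they do not

The generators produce data with exactly the statistical structure the
analysis assumes, so that every stage is testable offline and parameter
recovery is well-posed:

* `gen_satellite_record()` — SST = climatology + a spatially coherent
  AR(1) anomaly (persistence 0.9, stationary sd 0.9 °C, the scale of
  monthly Niño3 variability); true limitation affine in the anomaly with
  sensitivity `s_true` (default 0.03 °C⁻¹, clipped to [0, 0.78]);
  chlorophyll responding at −0.03 mg m⁻³ °C⁻¹ around 0.25 mg m⁻³ (so the
  mask retains ≥ 95% of pixels); yield = the inverse image of the
  limitation under the analysis-side scaling; nFLH = yield × chl /
  cos(SZA); 5% multiplicative noise on nFLH and chlorophyll, 0.05 °C on
  SST, 2% shared missing pixels. The record length (220 months) matches
  the satellite era the method is designed for.
* `gen_model_limitation()` — shares the scene's ENSO realization (paired
  forcing), with two phytoplankton groups offset around the target
  community limitation so the biomass weighting is exact before noise.
* `gen_ship_transect()` — radiance = smooth baseline + Gaussian emission
  peak (centre 683 nm, σ = 10 nm; the emission band is "about 680 nm",
  so the centre is a configuration choice) whose amplitude encodes
  yield × chl with the plateau ratio 3.5 between regimes; reflectance
  constructed so OC3 returns the configured chlorophyll; PAR from the
  clear-sky solar elevation at the ship position.
* `gen_bioassay()` — triplicate, mean-exact lognormal responses per
  treatment; the ±Fe active-yield contrast defaults to 3.2-fold.
* `gen_diel_frrf()` — regime-dependent dawn values, daytime NPQ
  depression, and night-time reductions (deep for Fe limitation, weak for
  N limitation), with the filtrate blank added to both Fo and Fm.

Not emulated: radiative transfer and atmospheric correction, glint, cloud
and coverage structure, seasonal cycles distinct from the ENSO mode,
phytoplankton community restructuring, grazing, and any model dynamics.
Passing the recovery tests therefore demonstrates that the *pipeline*
inverts its own stated data model under realistic noise — it does not
validate the ecophysiological interpretation of F/Chl against real ocean
variability, which rests on the field evidence the method was built on.

## Numerical choices

* **Band extraction.** The default is linear interpolation at the band
  centre: it is independent of the instrument's wavelength grid and makes
  FLH exactly invariant to affine-in-wavelength spectral components. A
  ±2 nm window mean is available where instrument noise favours
  averaging; on a grid containing the centres with neighbours > 2 nm away
  the two coincide.
* **Solar geometry.** Declination from the Spencer Fourier series and the
  hour angle directly from local apparent solar time; accuracy is a few
  hundredths of a degree at low latitudes (tested against an independent
  Meeus-based ephemeris to 0.5°), ample for monthly composites. Local
  solar time = UTC + longitude/15°, since ship clock conventions vary.
* **Ranged-MA degeneracies.** Zero range in either variable is an error
  (the ranging transform is undefined), not a silent fallback. A zero
  covariance on ranged data puts the major axis along a coordinate axis.
  The percentile bootstrap interval is widened, if needed, to contain the
  point estimate, and bootstrap resamples with zero range are redrawn.
* **Significance.** The regression p-value is the two-tailed test of the
  Pearson correlation: association significance does not depend on which
  symmetric slope estimator is drawn through the cloud. Whether the
  original analyses used parametric or permutation tests is not
  determinable, so a seeded permutation alternative is exposed
  (`n_permutations > 0`).
* **The affine scan limit.** With a purely affine scaling (lower anchor
  0) and an exactly scale-equivariant estimator, perturbing the upper
  anchor by ±10% moves the sensitivity ratio by exactly ±10% on clip-free
  data — the supremum of the scan impact. Any clipping attenuates the
  scaled slope and pushes the impact strictly below the scan percentage.
  Tests assert impact ≤ scan percentage.
* **t-test convention.** Welch by default (±Fe pools have no reason to
  share a variance); pooled by option. Samples with zero variance in both
  groups return p = 1 for equal means and p = 0 otherwise.
* **Degenerate light response.** A constant yield observed only at
  saturating PAR identifies the plateau (a is the value; b is
  unidentifiable and set so saturation holds at the lowest observed PAR);
  a constant yield including light-limited PAR is flagged degenerate.
* **Area weighting.** Regional means weight by cos(lat) — negligible
  within 5° of the equator but stated for completeness.
* **Anomaly mode.** "Value minus record average" is the default, taken
  literally; a monthly-climatology mode is provided without asserting
  that the seasonal cycle should be removed.
* **Night definition.** Astronomical (solar elevation < 0) by default; a
  PAR-threshold mode exists because "night-time" admits operational
  definitions.

## Problem sizes used by the test suite

The suite runs entirely on generated data: 220-month 1° Niño3 scenes (20
seeds for the recovery and ratio checks), 60-month coarse scenes for the
pipeline tests, 1000 random spectra for the FLH oracle, 100 random small
datasets for the ranged-MA oracle, 100-replicate coverage and null
simulations with a few hundred bootstrap resamples each, and 1–6-day
transects at 5-min cadence. These sizes were chosen so each property is
measured with comfortable Monte-Carlo margin while the whole suite stays
interactive.

## Known limitations

* The yield-to-limitation scaling is affine with configured anchors; the
  asymptote-detection procedure that motivates the upper anchor on global
  composites is not reimplemented here.
* The nFLH denormalization is a first-order geometric correction,
  validated for the low-latitude Pacific assumption of light-saturated
  fluorescence; at high latitudes (|lat| > 66° is outside the validated
  domain) the assumption fails.
* Gridded I/O uses a self-describing long-format CSV rather than NetCDF;
  the container and its readers validate axes and masks but do not aim at
  CF generality.
* The sensitivity ratio compares slopes only; attribution of an
  observed–model mismatch (iron recycling, community restructuring) is
  outside scope.
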