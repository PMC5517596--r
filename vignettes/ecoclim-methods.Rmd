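---
title: "ecoclim: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ecoclim: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoclim)
```

## The model in one paragraph

`ecoclim` scores each grid cell of a monthly climatology for maize
persistence on a 0–100 Ecoclimatic Index (EI). Growth is the product of two
weekly trapezoidal responses — temperature (on the weekly mean) and soil
moisture (on a bucket-model soil-moisture fraction) — integrated over 52
weeks into the annual growth index GI_A. Persistence is discounted by four
weekly-accumulated stresses (cold, heat, dry, wet);
`EI = GI_A × Π (1 − S/100)`. EI = 0 marks a cell where the population
cannot persist; 100 would require a greenhouse. Categories: 0 unsuitable,
(0, 10] marginal, (10, 20] medium, > 20 optimal.

## Parameters

The fitted maize parameter set (defaults of `maize_parameters()`):

| group | parameters | values | units |
|---|---|---|---|
| temperature response | DV0, DV1, DV2, DV3 | 10, 18, 30, 35 | °C |
| moisture response | SM0, SM1, SM2, SM3 | 0.1, 0.7, 0.9, 1.3 | fraction of holding capacity |
| cold stress | TTCS, THCS | 7, −0.00007 | °C, week⁻¹ |
| heat stress | TTHS, THHS | 40, 0.01 | °C, week⁻¹ |
| dry stress | SMDS, HDS | 0.1, −0.009 | fraction, week⁻¹ |
| wet stress | SMWS, HWS | 1.3, 0.001 | fraction, week⁻¹ |

DV0 = 10 °C is the conventional maize base temperature; DV3 = 35 °C the
point where dry-matter accumulation fails; SM0 = SMDS = 0.1 the permanent
wilting point; SM3 = SMWS = 1.3 marks waterlogging (the soil-moisture
fraction may exceed 1 when the profile is saturated beyond field capacity,
which is why the bucket ceiling `sm_cap` defaults to 2.0). Rate signs
follow the fitted set (negative for stresses that accumulate downward);
only magnitudes enter the accumulation.

## Numerical choices

**Weekly disaggregation.** The model year has 364 days (52 × 7; twelve
months of 30/31 days). State variables (temperatures, humidity) are
anchored at mid-month and interpolated linearly with cyclic wrap to week
midpoints; this is exact for constants and never leaves the monthly
min–max envelope. Precipitation is treated as a flux: each month's total is
spread uniformly over its days and summed into weeks, conserving the annual
total exactly. The upstream model's true internal interpolation scheme is
not documented in the sources available to us; linear interpolation is the
simplest scheme satisfying the properties above, and no result here depends
on its fine structure.

**Hydrology.** The bucket recursion
`sm[w] = clamp(sm[w−1] + (P_w − E_w)/capacity, 0, sm_cap)` uses
`capacity = 100 mm`, `sm_cap = 2`, and a humidity-deficit
evapotranspiration `E_w = 0.8 · max(Tavg_w, 0) · (1 − RH_w) · 7` mm/week.
The recursion is iterated over repeated annual cycles from sm = 0.5 until
the 52-week trace is stationary (tolerance 10⁻⁶, 50-year cap, warning on
failure). The map is monotone, so the attractor is independent of the
initial state — verified property-style in the tests. The reference
implementation's internal hydrology is not published; this minimal bucket
preserves every behaviour the analysis relies on (dry stress in deserts,
wet stress under perhumid regimes, seasonal growth windows) with all
constants exposed in `hydro_config()`.

**Stress accumulation.** Weekly exceedances beyond the threshold
accumulate as `100 · |rate| · Σ Δ_w c_w`, where `c_w` counts consecutive
stressed weeks ending at week w. The run count wraps across the year
boundary (a cold spell spanning December–January is one spell); if every
week is stressed the wrapped count is capped at 104, by which point any
realistic parameterisation has saturated at 100. The compounding reproduces
the documented accelerating character of stress accumulation; since the
exact published formula is unavailable, a `linear` switch (c ≡ 1) is
provided for comparison.

**Classification ties.** Bins are left-open/right-closed (10 is marginal,
10.001 medium). EI in (0, 1) — unassigned by the published bins — is folded
into marginal; consequently "suitable" means EI ≥ 1 in the area accounting,
with a strict `ei_gt_1` toggle available where the distinction matters.

**Annualisation order.** The EI equation is read as: annualise TI·MI into
GI_A first, then multiply by the annual stress discounts. The alternative
(weekly stress interaction) is not computable from annual stress indices;
the chosen order matches the printed form of the equation.

**Equal-area accounting.** Regional shares use exact spherical band areas
`R²Δλ(sin φ₊ − sin φ₋)` (R = 6371 km), which telescope to 4πR² globally
and are mathematically identical to shares computed after an equal-area
(Behrmann) re-projection — without any raster resampling.

## The synthetic world

`generate_world()` produces the stated test world: a 2° global grid with

- annual-mean temperature `27 − 0.55·|φ|` °C, seasonal amplitude
  `0.35·|φ|` peaking in July (north) / January (south), diurnal range 10 °C;
- zonal precipitation: wet tropics ≈ 180 mm/month within 10°, dry belts
  ≈ 15 mm/month at 15–35°, temperate ≈ 70 mm/month poleward of 40°, linear
  transitions between; a summer-peaking seasonal cycle of relative
  amplitude 0.3 (tropics, dry belt) and 0.6 (temperate);
- relative humidity 0.72 at the equator declining to 0.65 at the tropics
  edge, 0.35 in the dry belt, 0.60 temperate (09:00/15:00 = mean ± 0.07);
- seeded Gaussian noise (0.3 °C, 2 mm/month).

The humidity values were fixed at design time by water-balance analysis,
not tuned to tests afterwards: with the evapotranspiration formula above,
a flat tropical humidity makes the P−E balance change sign inside the
tropics, pinning soil moisture against a bound and wet-stress-excluding
most of the belt. Declining humidity keeps the tropical balance in slight
deficit everywhere, so the seasonal precipitation cycle walks soil moisture
through the growth band — yielding the intended geography: an optimal wet-
tropical core, dry-stress deserts, cold-excluded poles and marginal
mid-latitudes, with the cold boundary at ≈ 45–47° that moves poleward to
≈ 51–53° under a uniform +3.4 °C scenario.

What the generator deliberately does **not** emulate: real geography and
topography, ocean/land contrast (the default mask is all-land),
interannual variability, humidity seasonality and GCM spatial structure.
A green test on this world therefore establishes that the model mechanics
produce the right *qualitative* response surfaces (band geography,
monotone stress responses, poleward shift under warming), not that any
real-world suitability number is reproduced. Published full-scale area
tables depend on external 10′ climatologies and a curated occurrence
compilation, and are out of desk-scale reach by design.

## Scenario and validation machinery

`apply_scenario()` shifts temperatures by `dt_uniform +
dt_polar_amplification·|φ|` and scales precipitation per zone; identity
scenarios return the input bit-for-bit. `sample_occurrences()` draws
records from suitable cells with a contamination fraction (default 0.04)
from unsuitable cells, mirroring the observed ≈ 96% of presence records in
suitable categories; `overlay_fraction()` closes the loop, mapping points
to cells under half-open bounds ([west, east) × (south, north]) so edge
points are deterministic and never double-counted. `holdout_split()`
partitions records by a region mask the way a fit/validation split over a
reserved region is done when calibrating against real presences.

## Sensitivity analysis

`run_sensitivity()` is a one-at-a-time design: each parameter is perturbed
(defaults: ±1 °C for temperature thresholds, ±0.1 for moisture thresholds,
±10% magnitude for rates — the published analysis does not state its step
sizes, so ours are explicit in the report), the model is re-run, and the
percent change in suitable area (EI ≥ 1) is recorded. The weekly climate
and soil-moisture state are computed once and reused across the 32 runs —
valid because the hydrology does not depend on the species parameters.
Parameters are ranked by maximum range change, ties broken by name, and
labelled sensitive/insensitive against a 2% cutoff.

## File formats

Grids travel as a flat-text CSV dialect (one row per cell: `lon`, `lat`,
then `tmin01…tmin12, tmax01…, prec…, rh09…, rh15…`); single layers as
`lon,lat,value` CSV with a −9999 nodata sentinel. NetCDF and GeoTIFF are
declared in the interface but raise an informative error: no NetCDF/raster
backend is available in the supported dependency set, and the CSV dialect
round-trips bit-faithfully, which is the property the pipeline needs.

## Known limitations

- Evapotranspiration and bucket constants are plausible minimal choices,
  not a published hydrology; absolute soil-moisture traces should not be
  interpreted quantitatively.
- Stress compounding reproduces accelerating accumulation qualitatively;
  absolute stress values near the 0–100 interior depend on the unpublished
  accumulation form.
- The daily temperature cycle is collapsed to the weekly mean for growth
  (weekly min/max still drive cold/heat stress); cells whose growth hinges
  on sub-weekly structure are outside scope.
- No phenology, irrigation, CO₂ response, soils, pests or land use: this is
  a climate-suitability envelope, not a yield model.
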