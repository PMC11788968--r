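---
title: "Estimating root water uptake from diurnal soil-moisture cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating root water uptake from diurnal soil-moisture cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwudiel)
```

## The estimation problem

High-frequency soil-moisture sensors in a vegetated profile trace a
characteristic diel sawtooth during rain-free periods: water content
declines steeply while the canopy transpires and more gently at night,
when stomata are closed and only non-biological vertical flow (drainage,
capillary redistribution) continues. Under two working assumptions —

1. evapotranspiration is negligible at night, and
2. vertical flow is similar during day and night,

the night-time drying rate measures the vertical-flow background, and the
daytime drying *in excess of that background* is root water uptake (RWU).
`rwudiel` implements this estimator for a grassland profile instrumented at
several depths (defaults 3, 9, 18 and 36 cm at 15-min resolution), together
with everything the estimate depends on: sensor quality control, day/night
segmentation, day-eligibility rules, depth integration, VPD/SWC response
surfaces, uptake-capacity extraction and fine-root trait computation, plus
a forward simulator that provides ground truth.

## The estimators

For each sensor depth and date, ordinary least squares is fitted separately
to the day segment (sunrise to sunset) and the night segment (sunset to the
next sunrise, attributed to the evening's date, since it corrects that
day's slope). With signed slopes $s_d$ and $s_n$ (cm³ cm⁻³ h⁻¹, negative =
drying), daytime length $t_{day}$ (h) and a layer thickness $z$ (mm),

$$\mathrm{RWU} = (s_n - s_d)\, t_{day}\, z \quad [\mathrm{mm\,day^{-1}}].$$

Both slopes require at least 4 points; layers failing that yield an
undefined (not zero) estimate, and days with any undefined layer get no
profile total. Negative estimates — daytime wetting in excess of the night
trend — are retained and flagged rather than clipped, because clipping
would bias totals upward; consumers can filter on the flag.

The hourly variant replaces the daytime line with a cubic
$f(t) = a t + b t^2 + c t^3$ (time in hours since sunrise, free intercept
absorbed, at least 8 points). The derivative at each hour midpoint
$t_h = h - 0.5$ (the hour's mean rate, matching mm h⁻¹ units) replaces
$s_d$:

$$\mathrm{RWU}_h = (s_n - f'(t_h))\, z \quad [\mathrm{mm\,h^{-1}}],
\qquad h = 1, \dots, \lfloor t_{day} \rfloor.$$

Because hours are integers, the hourly grid tiles the daytime exactly only
when $t_{day}$ is an integer; with astronomical sun times the final
fraction of an hour before sunset is unrepresented. Hourly/daily
conservation is therefore tested on sun-time tables with integer day
lengths (where agreement is exact for linear trajectories and within a few
percent otherwise) and bounded at 10% in the general case.

**Layer scheme.** Sensors represent layers bounded by the midpoints between
neighbouring depths, with the 3 cm sensor covering the whole 0–6 cm zone
(including 0–3 cm) and the 36 cm sensor closing the 0–36 cm horizon:
thicknesses 60/75/135/90 mm. The scheme is configurable; totals are plain
sums of the thickness-scaled layer values and per-layer fractions are
reported when the total is positive.

**Uptake capacity.** For root-trait linkage, per-sensor hourly rates are
converted to rates per mm of soil, linearly interpolated across depth to
the midpoints of the 10-cm root-sampling layers (5, 15, 25 cm), rescaled to
100 mm, and maximised over all hours of the 10 days preceding a root
extraction — the realised capacity the roots in that layer supported,
typically approached after a rewetting event.

## Day eligibility

Estimates are accepted only for days with negligible precipitation
(daily total < 2 mm, strict: a 2.0 mm day is excluded) and outside periods
of reduced transpirational contribution: the cut day plus 14 days after
each grassland cut, and a configurable canopy-development window (default
21 days) after the snow-free date. Exclusion reasons are recorded with
precedence rain > post-cut > canopy development.

Rain can be totalled per calendar day (the default, matching how daily
precipitation is normally reported) or per diel window (sunrise to next
sunrise, attributed to the evening's date — the window whose rain actually
contaminates the night-slope correction). The conservative `"both"` option
excludes a day when either total reaches the threshold; the recovery
analyses in this package use it, because rain shortly after midnight
corrupts the previous evening's night segment while belonging to the next
calendar day.

## Quality control

The cleaning chain runs range filter → hourly-median smoothing → gap
filling → spike removal:

* **Range filter**: values outside the closed physical interval
  0–0.6 cm³ cm⁻³ become missing (`range_removed`). The boundary value 0.6
  is physically admissible and retained.
* **Smoothing**: each retained point is replaced by the median of its
  centred 1-h window (≤ 5 points), skipping missing values. A centred
  (rather than trailing) window is used since this is reanalysis, not
  real-time processing.
* **Gap filling**: missing runs up to 6 h (configurable) are linearly
  interpolated and flagged `gap_filled`; longer runs stay missing. The gap
  structure of real loggers is not well characterised, so gap lengths in
  the simulator are a free parameter.
* **Spike removal**: a point is a spike when its deviation from the
  windowed median exceeds `z_thresh` (default 5) times the window's MAD
  while neither neighbour does — the single-step criterion that separates
  sensor glitches (full recovery at the next step) from genuine wetting
  fronts, which elevate consecutive points. Defaults: 4-h window, z = 5;
  all parameters exposed. The finite window makes the MAD estimate noisy,
  so a small false-positive rate (≲ 0.5% of points) is expected and
  bounded in the tests at 1%.

Because the centred median already annihilates most single-step spikes,
the final detector mainly catches spikes adjacent to gaps; QC performance
is scored against the simulator's injection log as "artefact neutralised"
(flagged, or the injected displacement removed).

## The synthetic-data generator

The simulator is first-class, tested code: it defines the study conditions
under which the estimator is validated.

**Meteorology** (15-min grid): diel sinusoidal air temperature (default
15 ± 7 °C peaking at 14:00, day-to-day jitter 1.5 °C), relative humidity
anticorrelated with temperature (75 ± 20%, saturating at night), VPD from
the Magnus–Tetens formula
$e_s(T) = 0.6108\, e^{17.27 T / (T + 237.3)}$ kPa, and stochastic rain
(events on ~25% of days, mean depth 6 mm). The warming treatment adds its
offset (+3 °C) before VPD computation. A drought window suppresses natural
rain and ends with a single 40 mm rewetting at noon of its last day.

**Soil water**: a layered bucket on the sensor scheme. Rain infiltrates
top-down to field capacity after canopy interception (the first ~1.2 mm of
an event wets the canopy and evaporates — without this, sub-2-mm events
would reach the 3 cm sensor and corrupt days the rain rule rightly
accepts). Drainage removes $k(\theta - \theta_{fc})^+$ per hour day and
night, routed downward; an optional constant extra drainage term probes the
vertical-flow assumption directly. Defaults: porosity 0.55, field capacity
0.32, wilting point 0.08 cm³ cm⁻³, k = 0.02 h⁻¹.

**Transpiration sink** (daytime only, distributed 35/25/25/15% over the
layers):

$$S_i(t) = c(v)\,\min\!\Big(\frac{g\,v}{1 + v/v_{sat}},\, S_{max}\Big)\,
\beta(\theta_i)\, f_i,$$

with $v$ the VPD, a Lohammar-type stomatal saturation
($v_{sat} = 0.45$ kPa), an energy-limited ceiling
($S_{max} = 0.25$ mm h⁻¹, the midday plateau of grassland transpiration),
a linear soil-moisture stress ramp $\beta$ (0 at wilting point, 1 at
45% of the plant-available range — grasses transpire well into moderately
dry soil), and the elevated-CO₂ factor $c(v)$ (default 1; a treatment value
of, say, 0.8 applies only above the 1.9 kPa VPD threshold, mirroring
conductance down-regulation). The saturation and ceiling matter: a raw
$g \cdot v$ sink under a cosine VPD makes the daytime trajectory
S-shaped, and a straight line fitted to a sigmoid overestimates the mean
slope by ~20%; the plateau-shaped sink is both the realistic behaviour of
a C₃ grassland canopy and the regime in which the day/night slope
estimator is designed to work. Every booked flux is recorded, so water
balance closes to floating-point accuracy and nighttime uptake is exactly
zero by construction.

**Sensor artefacts**: Gaussian noise (default sd 0.002 cm³ cm⁻³),
single-step spikes (displacement 0.05, recovery next step), gap runs
(mean 8 steps) and out-of-range excursions, all position-logged for QC
scoring.

**Root cores**: per plot × period × 10-cm layer, fine-root dry mass
(0.15 g per top-layer core segment, halving with depth), SRL (100 m g⁻¹)
and diameter (0.4 mm) are drawn log-normally around treatment means;
length and projected area follow cylindrical geometry
(area = length × diameter), and a latent per-layer uptake capacity is
generated with configured linear couplings (+0.05 per mg cm⁻³ mass
density, +5·10⁻⁴ per m g⁻¹ SRL, −0.05 per mm diameter) for recovery
testing.

What the generator does *not* emulate: root plasticity (the sink weights
are fixed, so deep-uptake shifts arise purely from top-down drying),
hydraulic redistribution, Richards-equation dynamics, snow, interception
variability, and sensor calibration drift. Passing recovery tests
therefore show that the estimator chain is correct *under its own
assumptions*, not that those assumptions hold in any particular field
dataset.

## Response surfaces and hysteresis

Hourly profile totals on eligible days are joined with the
thickness-weighted profile-mean SWC and the hour-mean VPD. Two per-record
ratios are analysed in a crossed design: RWU/SWC (fraction of stored water
extracted per hour) averaged within VPD deciles, and RWU/VPD (a canopy
conductance proxy) within SWC deciles. Ratios are computed per record
*before* binning (robust to within-bin covariance; the alternative — a
ratio of bin means — is not what "RWU/SWC" denotes). Decile edges are
sample quantiles, assignment is by stable rank order (populations differ by
at most one when values are distinct), records with zero denominators are
excluded, and 95% intervals use the normal approximation within bins.
Deciles are pooled across treatments by default (switchable via
`group_cols`), so treatment contrasts compare means within common bins.

Near a VPD threshold, bin-level contrasts smear for two structural
reasons: hourly-mean-VPD bins just below the threshold contain 15-min
steps above it, and the whole-day cubic leaks a few percent of a midday
treatment effect into morning hours. Threshold behaviour should therefore
be read from deciles entirely above versus entirely below the threshold.

Diel hysteresis is quantified per day as the shoelace signed area of the
closed (VPD, RWU) polygon in hour order; zero area (a retraced path) is
degenerate, and the peak lag is the hour of maximum uptake minus the hour
of maximum VPD.

## Fine-root traits

Per core segment (4 cm diameter, 10 cm height): SRL = length/mass
(m g⁻¹), SRA = projected area/mass (m² g⁻¹; SRA = SRL × diameter exactly
for uniform cylinders), mass density = 1000·mass/volume (mg cm⁻³). The
fine-root-to-shoot production ratio divides 0–30 cm root mass by
aboveground biomass after normalising both to ground area (core footprint
vs 1 m² quadrat) — the normalisation makes the ratio dimensionless and
unit-invariant; a raw mass-over-mass compatibility mode exists.
Trait–capacity relations are simple OLS fits of per-layer uptake capacity
on one trait with additive per-layer offsets; mixed-effects treatment
inference is deliberately out of scope, the estimator exists to recover
slope magnitudes and signs.

## Numerical choices and degenerate inputs

* Slopes/cubics are undefined (never errors) below their point minima or
  on degenerate designs; undefined layers propagate to flagged,
  total-less profiles.
* Sunrise/sunset come from the standard NOAA solar-position equations
  (zenith 90.833°) at the site coordinates (47.496° N, 14.098° E,
  fixed UTC+1), with a verbatim table override for almanac times; polar
  latitudes are rejected.
* Timestamps are site-local, fixed-offset; days are site-local calendar
  days; all time arithmetic uses explicit hour units.
* All-identical decile inputs collapse to one flagged degenerate bin.
* Hysteresis areas below 10⁻¹² count as degenerate.
* The simulator aborts with a diagnostic if soil moisture leaves
  \[0, porosity\] (a step-size failure), and caps uptake and drainage so a
  well-posed configuration cannot go negative.

## Problem sizes

The validation scenarios are desk-scale by design: 30 simulated days, one
plot, four depths at 15-min resolution (11,520 sensor points) for recovery
and QC scoring; 20-day paired scenarios for treatment contrasts; 5-day
scenarios for the vertical-flow cancellation probe; 1,000 random segments
for the OLS oracle. On these sizes the full test suite and the acceptance
script each run in well under a minute of compute per scenario, and
recovery quality is insensitive to extending the span.

## Known limitations

* The linear day fit retains a small positive curvature bias (~5–10% on
  realistic plateau-shaped days); the cubic hourly variant reduces but
  does not remove it. This is a property of the published estimator, not
  of the implementation.
* With sensor noise of 0.002 cm³ cm⁻³, single-day totals carry a noise
  sd of roughly 0.3 mm day⁻¹ (dominated by the thick 13.5–27 cm layer),
  so day-level comparisons need averaging; segments reduced to near the
  4-point minimum by gaps can produce occasional wild estimates, which
  arrive flagged with their point counts.
* Fixed root-fraction weights understate drought uptake shifts relative
  to plastic root systems; the deep-layer fraction direction is robust,
  its magnitude is not transferable.
* The R/S normalisation assumes the core footprint and quadrat sample the
  same population density of roots and shoots.
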