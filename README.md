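# rwudiel

Root water uptake (RWU) estimation from diurnal soil-moisture
fluctuations, for grassland (or similar herbaceous) profiles instrumented
with multi-depth soil water content (SWC) sensors at sub-hourly
resolution. The package is aimed at ecohydrologists and plant
ecophysiologists who want transpiration-attributed uptake, its depth
distribution, and its coupling to atmospheric demand and fine-root traits
from sensor records alone — no lysimeters, sap flow or isotopes.

## The method

During rain-free periods, SWC declines steeply by day (root uptake +
vertical flow) and gently by night (vertical flow only, stomata closed).
Fitting separate ordinary-least-squares slopes to the day and night
segments of each diel cycle and correcting the day slope with the night
slope isolates the uptake. With signed slopes `s_day`, `s_night`
(cm³ cm⁻³ h⁻¹), daytime hours `t_day` and layer thickness `z` (mm):

    RWU       = (s_night − s_day) · t_day · z          [mm day⁻¹]
    RWU_h     = (s_night − f′(h − ½)) · z              [mm h⁻¹]

where `f(t) = a·t + b·t² + c·t³` is a cubic fit to the daytime trajectory
and `h = 1 … ⌊t_day⌋`. Day and night come from astronomical sunrise/sunset
(or a user table); days with ≥ 2 mm rain, 14 days after grassland cuts and
the canopy-development window after snowmelt are excluded. Per-depth
estimates are integrated over the 0–36 cm rooting horizon (sensors at
3/9/18/36 cm representing 60/75/135/90 mm layers). On top of this core the
package provides:

* the standard SWC cleaning chain (0–0.6 cm³ cm⁻³ range filter,
  hourly-median smoothing, gap filling, single-step spike removal);
* RWU/SWC across VPD deciles and RWU/VPD across SWC deciles, with diel
  RWU–VPD hysteresis loop metrics;
* per-layer maximum hourly uptake (`rwu_max`) over the 10 days before a
  root extraction;
* fine-root traits from ingrowth cores (SRL, SRA, mass density,
  root:shoot production) and their linear relations to uptake capacity;
* a multi-layer bucket simulator (VPD-driven plateau-shaped transpiration
  sink, drainage, rainfall with canopy interception, warming / stomatal
  down-regulation / rain-exclusion treatments, sensor artefacts) that
  provides ground truth for every stage.

See the vignette (`vignettes/rwu-estimation.Rmd`) for the model details
and design choices.

## Worked example

Simulate two weeks of a grassland scenario, corrupt it with sensor
artefacts, clean it, and estimate daily uptake:

```r
library(rwudiel)
library(dplyr)

cfg     <- scenario_config(n_days = 14, seed = 42)
met     <- generate_meteo(cfg)
sim     <- simulate_soil_profile(met, cfg)
noisy   <- apply_sensor_model(sim$swc, cfg)$swc
cleaned <- clean_swc(noisy)
elig    <- eligible_days(met, window = "both", suntimes = sim$suntimes)

prof <- rwu_daily(cleaned, sim$suntimes, cfg$scheme, eligibility = elig) |>
  integrate_profile(cfg$scheme)

prof |>
  filter(complete) |>
  distinct(date, total) |>
  left_join(sim$daily_truth, by = "date")
#> # A tibble: 10 × 3
#>   date       total transpiration_mm
#>   <date>     <dbl>            <dbl>
#> 1 2020-06-01  3.86             3.59
#> 2 2020-06-03  3.42             3.56
#> 3 2020-06-04  3.95             3.76
#> 4 2020-06-05  4.23             3.74
#> 5 2020-06-06  3.50             3.30
#> # ℹ 5 more rows
```

`total` is the estimated depth-integrated uptake (mm day⁻¹) recovered from
the corrupted sensor series; `transpiration_mm` is the simulator's booked
truth. Rain days (here 2020-06-02) are excluded by the < 2 mm rule. The QC
chain reports what it changed:

```r
qc_summary(cleaned)
#> # A tibble: 5 × 3
#>   qc_flag           n fraction
#>   <fct>         <int>    <dbl>
#> 1 ok             5306  0.987
#> 2 range_removed     0  0
#> 3 gap_filled       44  0.00818
#> 4 spike_removed    26  0.00484
#> 5 missing           0  0
```

Downstream, `rwu_hourly()` + `build_hourly_join()` feed `ratio_table()`
(decile response surfaces, plotted with `autoplot()`),
`hysteresis_metrics()`, and `rwu_max()`; `generate_root_cores()` +
`root_traits()` + `trait_rwu_relation()` link uptake capacity to fine-root
traits (`tidy()`/`glance()` methods included). `run_pipeline()` executes
the whole chain into a directory of long-format CSVs with a run manifest.

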