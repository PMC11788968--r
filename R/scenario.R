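#' Sensor-depth to soil-layer mapping for the rooting horizon
#'
#' Each soil-moisture sensor is taken to represent one layer of the 0-36 cm
#' main rooting horizon. Default boundaries are the midpoints between
#' neighbouring sensors, with the shallowest sensor (3 cm) covering the
#' 0-3 cm zone as well, so the layers tile the horizon without overlap:
#' 3 cm -> 0-6 cm, 9 cm -> 6-13.5 cm, 18 cm -> 13.5-27 cm, 36 cm -> 27-36 cm
#' (thicknesses 60/75/135/90 mm, summing to 360 mm).
#'
#' @param sensor_depth_cm sensor depths in cm, strictly increasing.
#' @param horizon_cm bottom of the integration horizon in cm.
#' @return A tibble with columns `depth_cm`, `top_cm`, `bottom_cm`,
#'   `thickness_mm`.
#' @examples
#' layer_scheme()
#' @export
layer_scheme <- function(sensor_depth_cm = c(3, 9, 18, 36), horizon_cm = 36) {
  d <- sort(unique(sensor_depth_cm))
  if (length(d) < 1L) abort("at least one sensor depth is required")
  if (max(d) > horizon_cm) abort("sensor depths must lie within the horizon")
  mid <- if (length(d) > 1L) (d[-length(d)] + d[-1L]) / 2 else numeric(0)
  top <- c(0, mid)
  bottom <- c(mid, horizon_cm)
  tibble(
    depth_cm = d,
    top_cm = top,
    bottom_cm = bottom,
    thickness_mm = (bottom - top) * 10
  )
}

#' Simulation scenario configuration
#'
#' Bundles every knob of the synthetic study: span, meteorological forcing,
#' treatment flags (warming offset, stomatal down-regulation under elevated
#' CO2, rain-exclusion drought with rewetting), soil hydraulic parameters of
#' the layered bucket model, the root-profile sink weights, sensor-artefact
#' rates, and the seed. Defaults emulate a montane C3 grassland growing
#' season: diel air temperature 15 +/- 7 degC peaking at 14:00, relative
#' humidity anticorrelated with temperature (saturating at night), rain on
#' about a quarter of days with ~6 mm mean event depth, a transpiration sink
#' of ~2.5-3.5 mm per day distributed 35/25/25/15% over the four sensor
#' layers, and loamy-sand water constants (porosity 0.55, field capacity
#' 0.32, wilting point 0.10).
#'
#' @param n_days simulated span in days (>= 1).
#' @param start_date first simulated date.
#' @param warming_offset canopy warming in degC added to air temperature
#'   before VPD computation (the warming treatment applies +3).
#' @param eco2_factor multiplicative stomatal down-regulation of the sink
#'   gain in (0, 1]; 1 = ambient. Applied only above `eco2_vpd_threshold`.
#' @param eco2_vpd_threshold VPD threshold (kPa) above which the elevated-CO2
#'   down-regulation acts.
#' @param drought `NULL`, or `list(start_day, end_day, rewet_mm)`: natural
#'   rain is excluded on days `start_day..end_day` (1-based indices into the
#'   span) and a single rewetting event of `rewet_mm` mm (default 40) falls
#'   at noon of the end day.
#' @param meteo list of diel-forcing parameters: `t_mean`, `t_amp`,
#'   `t_peak_hour`, `t_day_sd` (day-to-day temperature jitter sd),
#'   `rh_mean`, `rh_amp`, `rh_day_sd`, `rain_prob` (per-day event
#'   probability), `rain_mean_mm` (mean event depth), `interception_mm`
#'   (canopy interception storage: the first ~1 mm of each event wets the
#'   canopy and evaporates without reaching the soil).
#' @param soil list: `porosity`, `field_capacity`, `wilting_point`
#'   (cm3 cm-3), `drainage_k` (h-1 linear drainage of water above field
#'   capacity), `stress_frac` (position of the critical point of the
#'   root-stress ramp between wilting point and field capacity),
#'   `init_theta` (initial water content, recycled over layers),
#'   `extra_drainage` (constant additional drainage, cm3 cm-3 h-1, applied
#'   day and night; used to probe the estimator's vertical-flow assumption).
#' @param sink_gain canopy conductance-like gain g of the daytime sink,
#'   mm h-1 kPa-1 for the whole profile at low VPD.
#' @param vpd_sat stomatal saturation constant (kPa) of the Lohammar-type
#'   conductance response: the unstressed sink is
#'   g * vpd / (1 + vpd / vpd_sat), rising steeply at low VPD and
#'   saturating as stomata down-regulate at high VPD.
#' @param sink_max energy-limited ceiling of the profile sink, mm h-1
#'   (transpiration cannot exceed the radiation-limited rate, giving the
#'   characteristic midday plateau).
#' @param root_fraction per-layer sink weights, summing to 1.
#' @param scheme sensor/layer scheme from [layer_scheme()].
#' @param sensor list of artefact rates: `noise_sd` (cm3 cm-3), `spike_prob`
#'   (per point), `spike_mag` (displacement, cm3 cm-3), `gap_prob` (per-point
#'   probability that a gap run starts), `gap_mean_steps` (mean gap length),
#'   `oor_frac` (fraction of points pushed outside the physical 0-0.6 range).
#' @param latitude,longitude,tz site coordinates and (fixed-offset) timezone.
#' @param seed integer seed driving every random draw of the generators.
#' @return A validated list of class `scenario_config`.
#' @examples
#' cfg <- scenario_config(n_days = 5, seed = 42)
#' cfg$soil$field_capacity
#' @export
scenario_config <- function(n_days = 30,
                            start_date = as.Date("2020-06-01"),
                            warming_offset = 0,
                            eco2_factor = 1,
                            eco2_vpd_threshold = 1.9,
                            drought = NULL,
                            meteo = list(),
                            soil = list(),
                            sink_gain = 1.0,
                            vpd_sat = 0.45,
                            sink_max = 0.25,
                            root_fraction = c(0.35, 0.25, 0.25, 0.15),
                            scheme = layer_scheme(),
                            sensor = list(),
                            latitude = SITE_LAT,
                            longitude = SITE_LON,
                            tz = SITE_TZ,
                            seed = 1L) {
  meteo_def <- list(
    t_mean = 15, t_amp = 7, t_peak_hour = 14, t_day_sd = 1.5,
    rh_mean = 75, rh_amp = 20, rh_day_sd = 4,
    rain_prob = 0.25, rain_mean_mm = 6, interception_mm = 1.2
  )
  soil_def <- list(
    porosity = 0.55, field_capacity = 0.32, wilting_point = 0.08,
    drainage_k = 0.02, stress_frac = 0.45, init_theta = 0.34,
    extra_drainage = 0
  )
  sensor_def <- list(
    noise_sd = 0.002, spike_prob = 0.001, spike_mag = 0.05,
    gap_prob = 5e-4, gap_mean_steps = 8, oor_frac = 0
  )
  bad_meteo <- setdiff(names(meteo), names(meteo_def))
  bad_soil <- setdiff(names(soil), names(soil_def))
  bad_sensor <- setdiff(names(sensor), names(sensor_def))
  if (length(c(bad_meteo, bad_soil, bad_sensor)) > 0L) {
    abort(sprintf("unknown scenario key(s): %s",
                  paste(c(bad_meteo, bad_soil, bad_sensor), collapse = ", ")))
  }
  meteo <- utils::modifyList(meteo_def, meteo)
  soil <- utils::modifyList(soil_def, soil)
  sensor <- utils::modifyList(sensor_def, sensor)

  if (!is.numeric(n_days) || n_days < 1) abort("n_days must be >= 1")
  n_days <- as.integer(n_days)
  if (abs(sum(root_fraction) - 1) > 1e-9) {
    abort("root_fraction must sum to 1 (within 1e-9)")
  }
  if (length(root_fraction) != nrow(scheme)) {
    abort("root_fraction must have one weight per sensor layer")
  }
  with(soil, {
    if (!(wilting_point < field_capacity)) abort("wilting point must be < field capacity")
    if (!(field_capacity <= porosity)) abort("field capacity must be <= porosity")
    if (!(porosity <= 0.6)) abort("porosity must be <= 0.6")
  })
  if (!is.null(drought)) {
    if (!all(c("start_day", "end_day") %in% names(drought))) {
      abort("drought must supply start_day and end_day")
    }
    drought$rewet_mm <- drought$rewet_mm %||% 40
    if (drought$start_day < 1 || drought$end_day > n_days ||
        drought$start_day > drought$end_day) {
      abort("drought window lies outside the simulation span")
    }
  }
  if (eco2_factor <= 0 || eco2_factor > 1) abort("eco2_factor must be in (0, 1]")
  if (sensor$noise_sd < 0) abort("sensor noise_sd must be >= 0")

  structure(
    list(
      n_days = n_days, start_date = as.Date(start_date),
      warming_offset = warming_offset,
      eco2_factor = eco2_factor, eco2_vpd_threshold = eco2_vpd_threshold,
      drought = drought, meteo = meteo, soil = soil,
      sink_gain = sink_gain, vpd_sat = vpd_sat, sink_max = sink_max,
      root_fraction = root_fraction,
      scheme = scheme, sensor = sensor,
      latitude = latitude, longitude = longitude, tz = tz,
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
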