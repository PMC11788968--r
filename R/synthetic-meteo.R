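#' Vapour pressure deficit from air temperature and relative humidity
#'
#' Saturation vapour pressure follows the Magnus-Tetens formula
#' es(T) = 0.6108 * exp(17.27 T / (T + 237.3)) kPa, the standard
#' micrometeorological choice; VPD = es(T) * (1 - RH/100).
#'
#' @param air_temp air temperature, degC.
#' @param rel_humidity relative humidity, percent in \[0, 100\].
#' @return VPD in kPa (>= 0), vectorised over the inputs.
#' @examples
#' vpd_from_t_rh(25, 50)
#' vpd_from_t_rh(20, 100) # saturated air: 0
#' @export
vpd_from_t_rh <- function(air_temp, rel_humidity) {
  if (any(rel_humidity < 0 | rel_humidity > 100, na.rm = TRUE)) {
    abort("rel_humidity must lie in [0, 100]")
  }
  es <- 0.6108 * exp(17.27 * air_temp / (air_temp + 237.3))
  pmax(es * (1 - rel_humidity / 100), 0)
}

#' Generate synthetic canopy meteorology
#'
#' Produces a 15-min meteorological forcing series for a scenario: diel
#' sinusoidal air temperature (with day-to-day jitter and the warming
#' treatment's offset applied before VPD computation), relative humidity
#' anticorrelated with temperature and saturating at night, VPD from
#' [vpd_from_t_rh()], and stochastic rainfall. Inside a drought window
#' natural rain is excluded and a single rewetting event of the configured
#' depth falls at noon of the window's last day.
#'
#' @param config a [scenario_config()].
#' @return A tibble with columns `timestamp` (site-local POSIXct, 15-min
#'   grid), `air_temp` (degC), `rel_humidity` (percent), `vpd` (kPa) and
#'   `precip` (mm per 15-min step).
#' @examples
#' met <- generate_meteo(scenario_config(n_days = 2, seed = 7))
#' range(met$vpd)
#' @export
generate_meteo <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  m <- config$meteo
  steps_per_day <- 96L
  n <- config$n_days * steps_per_day
  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = config$tz)
  timestamp <- t0 + (seq_len(n) - 1L) * 900
  hod <- (seq_len(n) - 1L) %% steps_per_day / 4 # hour of day, 0..23.75
  day_idx <- (seq_len(n) - 1L) %/% steps_per_day + 1L

  with_seed(config$seed, {
    t_off <- rnorm(config$n_days, 0, m$t_day_sd)
    rh_off <- rnorm(config$n_days, 0, m$rh_day_sd)
    diel <- cos(2 * pi * (hod - m$t_peak_hour) / 24)
    air_temp <- m$t_mean + config$warming_offset + t_off[day_idx] + m$t_amp * diel
    rel_humidity <- clamp(m$rh_mean + rh_off[day_idx] - m$rh_amp * diel, 5, 100)

    precip <- numeric(n)
    rain_day <- runif(config$n_days) < m$rain_prob
    for (d in which(rain_day)) {
      depth <- rexp(1, 1 / m$rain_mean_mm)
      len <- sample(4:12, 1)
      start <- (d - 1L) * steps_per_day + sample.int(steps_per_day - len, 1)
      sel <- start + seq_len(len) - 1L
      precip[sel] <- precip[sel] + depth / len
    }
    if (!is.null(config$drought)) {
      dr <- config$drought
      in_window <- day_idx >= dr$start_day & day_idx <= dr$end_day
      precip[in_window] <- 0
      rewet_at <- (dr$end_day - 1L) * steps_per_day + 48L # noon of the end day
      precip[rewet_at] <- dr$rewet_mm
    }
    tibble(
      timestamp = timestamp,
      air_temp = air_temp,
      rel_humidity = rel_humidity,
      vpd = vpd_from_t_rh(air_temp, rel_humidity),
      precip = precip
    )
  })
}
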