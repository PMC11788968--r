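#' Astronomical sunrise and sunset times
#'
#' Computes geometric sunrise/sunset (solar zenith 90.833 deg, i.e. standard
#' refraction-corrected rise/set) for each date from the NOAA solar position
#' equations: fractional year, equation of time, solar declination and hour
#' angle. Alternatively a user-supplied sunrise/sunset table is passed
#' through verbatim, for sites that prefer almanac times.
#'
#' @param dates a `Date` vector.
#' @param latitude,longitude site coordinates in decimal degrees
#'   (east/north positive). Defaults are the package's reference montane
#'   grassland site (47.496 N, 14.098 E).
#' @param tz fixed-offset timezone of the returned timestamps.
#' @param table optional override: a data frame with columns `date`,
#'   `sunrise`, `sunset` (POSIXct, or "HH:MM" strings interpreted on
#'   `date` in `tz`). Rows are used verbatim.
#' @return A tibble with columns `date`, `sunrise`, `sunset` (POSIXct in
#'   `tz`) and `t_day` (daytime hours, sunset minus sunrise).
#' @examples
#' compute_sun_times(as.Date("2020-03-20"))
#' @export
compute_sun_times <- function(dates,
                              latitude = SITE_LAT, longitude = SITE_LON,
                              tz = SITE_TZ, table = NULL) {
  if (!is.null(table)) {
    assert_cols(table, c("date", "sunrise", "sunset"), "sun-times table")
    tab <- as_tibble(table)
    if (is.character(tab$sunrise)) {
      tab$sunrise <- as.POSIXct(paste(tab$date, tab$sunrise), tz = tz)
      tab$sunset <- as.POSIXct(paste(tab$date, tab$sunset), tz = tz)
    }
    tab$t_day <- as.numeric(difftime(tab$sunset, tab$sunrise, units = "hours"))
    if (any(tab$t_day <= 0 | tab$t_day >= 24)) abort("sun table: need 0 < t_day < 24")
    return(tab[c("date", "sunrise", "sunset", "t_day")])
  }
  dates <- as.Date(dates)
  doy <- as.integer(format(dates, "%j"))
  gam <- 2 * pi / 365 * (doy - 1)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gam) - 0.032077 * sin(gam) -
                        0.014615 * cos(2 * gam) - 0.040849 * sin(2 * gam))
  decl <- 0.006918 - 0.399912 * cos(gam) + 0.070257 * sin(gam) -
    0.006758 * cos(2 * gam) + 0.000907 * sin(2 * gam) -
    0.002697 * cos(3 * gam) + 0.00148 * sin(3 * gam)
  lat_r <- latitude * pi / 180
  cos_ha <- cos(90.833 * pi / 180) / (cos(lat_r) * cos(decl)) -
    tan(lat_r) * tan(decl)
  if (any(abs(cos_ha) > 1)) {
    abort("polar day/night at this latitude and date: no sunrise/sunset")
  }
  ha_deg <- acos(cos_ha) * 180 / pi
  sunrise_utc_min <- 720 - 4 * (longitude + ha_deg) - eqtime
  sunset_utc_min <- 720 - 4 * (longitude - ha_deg) - eqtime
  midnight_utc <- as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")
  sunrise <- as.POSIXct(as.numeric(midnight_utc) + sunrise_utc_min * 60,
                        origin = "1970-01-01", tz = tz)
  sunset <- as.POSIXct(as.numeric(midnight_utc) + sunset_utc_min * 60,
                       origin = "1970-01-01", tz = tz)
  tibble(
    date = dates, sunrise = sunrise, sunset = sunset,
    t_day = as.numeric(difftime(sunset, sunrise, units = "hours"))
  )
}

#' Attribute each observation to a diel (day/night) segment
#'
#' Day points lie in \[sunrise, sunset) of their calendar date; night points
#' run from sunset to the next sunrise and are attributed to the evening's
#' date, so a night crossing midnight corrects that same day's daytime
#' slope. Points before the first listed sunrise are attributed to the
#' previous (unlisted) date's night.
#'
#' @param series a soil-moisture tibble with at least `timestamp`; any other
#'   columns are carried through.
#' @param suntimes output of [compute_sun_times()] covering the series'
#'   dates.
#' @return The input with added columns `date` (diel-attributed) and
#'   `phase` ("day"/"night").
#' @export
segment_day_night <- function(series, suntimes) {
  assert_cols(series, "timestamp", "series")
  assert_cols(suntimes, c("date", "sunrise", "sunset"), "suntimes")
  cal <- local_date(series$timestamp)
  st <- suntimes[match(cal, suntimes$date), ]
  if (anyNA(st$date)) abort("suntimes does not cover every date in the series")
  is_day <- series$timestamp >= st$sunrise & series$timestamp < st$sunset
  before_sunrise <- series$timestamp < st$sunrise
  out <- series
  out$date <- cal
  out$date[!is_day & before_sunrise] <- cal[!is_day & before_sunrise] - 1L
  out$phase <- ifelse(is_day, "day", "night")
  as_tibble(out)
}

#' Select estimation-eligible days
#'
#' A day is ineligible when its precipitation total reaches the rain
#' threshold (the estimator accepts only days with negligible rain,
#' < 2 mm), when it falls within the post-cut regrowth exclusion (the cut
#' day and the following `post_cut_days` days), or within the
#' canopy-development window after the snow-free date. Reasons are recorded
#' with precedence rain > post_cut > canopy_development.
#'
#' Precipitation is aggregated per site-local calendar day by default.
#' `window = "diel"` instead totals rain over \[sunrise, next sunrise),
#' attributed to the evening's date — the window whose rain can corrupt the
#' day's night-slope correction — and requires `suntimes`. `window =
#' "both"` excludes a day when either total reaches the threshold (the
#' conservative choice for estimation, since rain near midnight
#' contaminates the night segment of one date and the calendar total of
#' another); the reported `precip_mm` is then the larger of the two.
#'
#' @param meteo tibble with `timestamp` and `precip` (mm per step).
#' @param cut_dates `Date` vector of grassland cut dates (duplicates or cuts
#'   spaced closer than the exclusion window are rejected).
#' @param snow_free_date optional `Date`: start of canopy development.
#' @param rain_mm rain threshold in mm; days with total >= this are excluded.
#' @param post_cut_days days excluded after each cut (in addition to the cut
#'   day itself).
#' @param canopy_dev_days length of the canopy-development exclusion.
#' @param window `"calendar"` or `"diel"` precipitation aggregation.
#' @param suntimes required when `window = "diel"`.
#' @return A tibble with one row per calendar day: `date`, `precip_mm`,
#'   `eligible`, `exclusion_reason` in
#'   `{none, rain, post_cut, canopy_development}`.
#' @examples
#' met <- generate_meteo(scenario_config(n_days = 5, seed = 1))
#' eligible_days(met)
#' @export
eligible_days <- function(meteo, cut_dates = NULL, snow_free_date = NULL,
                          rain_mm = 2, post_cut_days = 14,
                          canopy_dev_days = 21,
                          window = c("calendar", "diel", "both"),
                          suntimes = NULL) {
  assert_cols(meteo, c("timestamp", "precip"), "meteo")
  window <- match.arg(window)
  if (!is.null(cut_dates)) {
    cut_dates <- as.Date(cut_dates)
    if (anyDuplicated(cut_dates)) abort("duplicate cut dates")
    if (length(cut_dates) > 1L &&
        any(diff(sort(cut_dates)) <= post_cut_days)) {
      abort("cut dates closer than the post-cut exclusion window overlap")
    }
  }
  all_dates <- sort(unique(local_date(meteo$timestamp)))
  calendar_totals <- tibble(date = local_date(meteo$timestamp),
                            precip = meteo$precip) |>
    group_by(.data$date) |>
    summarise(precip_mm = sum(.data$precip, na.rm = TRUE), .groups = "drop")
  if (window == "calendar") {
    totals <- calendar_totals
  } else {
    if (is.null(suntimes)) {
      abort(sprintf("window = '%s' requires suntimes", window))
    }
    diel_totals <- segment_day_night(meteo, suntimes) |>
      group_by(.data$date) |>
      summarise(precip_mm = sum(.data$precip, na.rm = TRUE), .groups = "drop")
    totals <- if (window == "diel") diel_totals else {
      bind_rows(calendar_totals, diel_totals) |>
        group_by(.data$date) |>
        summarise(precip_mm = max(.data$precip_mm), .groups = "drop")
    }
  }
  out <- tibble(date = all_dates) |>
    left_join(totals, by = "date") |>
    mutate(precip_mm = dplyr::coalesce(.data$precip_mm, 0))

  reason <- rep("none", nrow(out))
  if (!is.null(snow_free_date)) {
    since_snow <- as.integer(out$date - as.Date(snow_free_date))
    reason[since_snow >= 0 & since_snow <= canopy_dev_days] <- "canopy_development"
  }
  if (!is.null(cut_dates) && length(cut_dates) > 0L) {
    in_cut <- vapply(out$date, function(d) {
      any(as.integer(d - cut_dates) >= 0 & as.integer(d - cut_dates) <= post_cut_days)
    }, logical(1))
    reason[in_cut] <- "post_cut"
  }
  reason[out$precip_mm >= rain_mm] <- "rain"
  out$eligible <- reason == "none"
  out$exclusion_reason <- reason
  out
}
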