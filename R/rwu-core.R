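#' Ordinary least-squares slope of a diel soil-moisture segment
#'
#' Fits swc ~ time (hours) by OLS. A slope is defined only when at least
#' `min_points` non-missing observations with non-degenerate times are
#' available; otherwise the segment is returned undefined (`NA` slope), not
#' an error — sparse segments are an expected, flagged outcome.
#'
#' @param t_hours numeric time in hours (any origin).
#' @param swc soil water content, cm3 cm-3.
#' @param min_points minimum observations (the estimator requires >= 4).
#' @return A one-row tibble: `n`, `slope` (cm3 cm-3 h-1), `intercept`,
#'   `resid_sd`.
#' @examples
#' fit_linear_slope(0:9, 0.30 - 0.001 * (0:9))
#' @export
fit_linear_slope <- function(t_hours, swc, min_points = 4L) {
  keep <- !is.na(t_hours) & !is.na(swc)
  t <- t_hours[keep]
  y <- swc[keep]
  n <- length(y)
  if (n < min_points || length(unique(t)) < 2L) {
    return(tibble(n = n, slope = NA_real_, intercept = NA_real_,
                  resid_sd = NA_real_))
  }
  fit <- lm(y ~ t)
  tibble(
    n = n,
    slope = unname(coef(fit)[["t"]]),
    intercept = unname(coef(fit)[["(Intercept)"]]),
    resid_sd = sqrt(sum(fit$residuals^2) / max(1L, n - 2L))
  )
}

#' Fit day and night linear slopes per sensor and date
#'
#' @param segments output of [segment_day_night()] (columns `plot_id`,
#'   `depth_cm`, `date`, `phase`, `timestamp`, `swc`).
#' @param min_points minimum points per segment.
#' @return Tibble keyed by plot, depth, date and phase with `n`, `slope`
#'   (cm3 cm-3 h-1) and `resid_sd`.
#' @export
fit_diel_slopes <- function(segments, min_points = 4L) {
  assert_cols(segments, c("date", "phase", "timestamp", "swc"), "segments")
  keys <- intersect(c("plot_id", "treatment", "depth_cm", "date", "phase"),
                    names(segments))
  segments |>
    group_by(dplyr::pick(dplyr::all_of(keys))) |>
    group_modify(function(df, key) {
      t <- as.numeric(difftime(df$timestamp, df$timestamp[1L], units = "hours"))
      fit_linear_slope(t, df$swc, min_points = min_points)
    }) |>
    ungroup()
}

#' Daily layer uptake from day and night slopes
#'
#' The estimator's core identity: the daytime drawdown in excess of the
#' night trend is root water uptake. With signed slopes (negative =
#' drying), uptake = (slope_night - slope_day) * t_day * thickness, in mm
#' per day. Identical vertical flow day and night cancels in the
#' difference; negative results (daytime wetting beyond the night trend)
#' are retained for the caller to flag, never clipped.
#'
#' @param slope_day,slope_night signed slopes, cm3 cm-3 h-1.
#' @param t_day daytime hours.
#' @param thickness_mm layer thickness, mm.
#' @return Uptake, mm day-1 (vectorised).
#' @examples
#' daily_rwu_layer(-0.002, 0, t_day = 12, thickness_mm = 100) # 2.4 mm/day
#' @export
daily_rwu_layer <- function(slope_day, slope_night, t_day, thickness_mm) {
  (slope_night - slope_day) * t_day * thickness_mm
}

#' Daily root water uptake per sensor layer
#'
#' Segments the cleaned series into day/night, fits per-segment linear
#' slopes, corrects each day slope with the same date's night slope and
#' scales by daytime hours and layer thickness. Days failing the
#' minimum-point rule at a depth yield an undefined layer estimate there.
#'
#' @param swc_clean cleaned series ([clean_swc()]).
#' @param suntimes [compute_sun_times()] table covering the span.
#' @param scheme [layer_scheme()] mapping sensors to layers.
#' @param eligibility optional [eligible_days()] table; ineligible dates are
#'   dropped.
#' @param min_points minimum points per linear segment.
#' @return Tibble per plot x date x depth: segment sizes, slopes,
#'   `rwu_mm_day` and a `negative` flag.
#' @export
rwu_daily <- function(swc_clean, suntimes, scheme = layer_scheme(),
                      eligibility = NULL, min_points = 4L) {
  slopes <- segment_day_night(swc_clean, suntimes) |>
    fit_diel_slopes(min_points = min_points)
  keys <- intersect(c("plot_id", "treatment", "depth_cm", "date"), names(slopes))
  wide <- slopes |>
    select(dplyr::all_of(keys), "phase", "n", "slope") |>
    tidyr::pivot_wider(names_from = "phase", values_from = c("n", "slope"))
  for (col in c("n_day", "n_night", "slope_day", "slope_night")) {
    if (!col %in% names(wide)) wide[[col]] <- if (grepl("^n_", col)) 0L else NA_real_
  }
  out <- wide |>
    inner_join(suntimes[c("date", "t_day")], by = "date") |>
    inner_join(scheme[c("depth_cm", "thickness_mm")], by = "depth_cm") |>
    mutate(
      rwu_mm_day = daily_rwu_layer(.data$slope_day, .data$slope_night,
                                   .data$t_day, .data$thickness_mm),
      negative = !is.na(.data$rwu_mm_day) & .data$rwu_mm_day < 0
    ) |>
    arrange(dplyr::pick(dplyr::all_of(keys)))
  if (!is.null(eligibility)) {
    out <- out |>
      inner_join(eligibility[c("date", "eligible")], by = "date") |>
      filter(.data$eligible) |>
      select(-"eligible")
  }
  out
}

#' Cubic fit to a daytime soil-moisture trajectory
#'
#' Least-squares fit of swc to t + t^2 + t^3 (t in hours since sunrise)
#' with a free intercept, which is absorbed before coefficient extraction.
#' Requires at least `min_points` (the hourly estimator needs >= 8);
#' rank-deficient designs return an undefined fit.
#'
#' @param t_hours hours since sunrise.
#' @param swc soil water content.
#' @param min_points minimum observations.
#' @return One-row tibble: `n`, `a`, `b`, `c` (units cm3 cm-3 h-1, h-2,
#'   h-3).
#' @export
fit_day_polynomial <- function(t_hours, swc, min_points = 8L) {
  keep <- !is.na(t_hours) & !is.na(swc)
  t <- t_hours[keep]
  y <- swc[keep]
  n <- length(y)
  undefined <- tibble(n = n, a = NA_real_, b = NA_real_, c = NA_real_)
  if (n < min_points || length(unique(t)) < 4L) return(undefined)
  fit <- lm(y ~ t + I(t^2) + I(t^3))
  cf <- coef(fit)
  if (anyNA(cf)) return(undefined)
  tibble(n = n, a = unname(cf[["t"]]), b = unname(cf[["I(t^2)"]]),
         c = unname(cf[["I(t^3)"]]))
}

#' Fit daytime cubic models per sensor and date
#'
#' @param segments output of [segment_day_night()]; only `phase == "day"`
#'   rows are used.
#' @param suntimes sun-times table (for the hours-since-sunrise origin).
#' @param min_points minimum points per day fit.
#' @return Tibble keyed by plot, depth and date with `n`, `a`, `b`, `c`.
#' @export
fit_day_polynomials <- function(segments, suntimes, min_points = 8L) {
  keys <- intersect(c("plot_id", "treatment", "depth_cm", "date"),
                    names(segments))
  segments |>
    filter(.data$phase == "day") |>
    inner_join(suntimes[c("date", "sunrise")], by = "date") |>
    group_by(dplyr::pick(dplyr::all_of(keys))) |>
    group_modify(function(df, key) {
      t <- as.numeric(difftime(df$timestamp, df$sunrise[1L], units = "hours"))
      fit_day_polynomial(t, df$swc, min_points = min_points)
    }) |>
    ungroup()
}

#' Hourly layer uptake from a daytime cubic and the night slope
#'
#' The cubic's derivative a + 2bt + 3ct^2, evaluated at the hour midpoint
#' t = h - 0.5 (the hour's mean rate), replaces the daily linear day slope:
#' uptake_h = (slope_night - f'(h - 0.5)) * thickness, mm h-1.
#'
#' @param a,b,c cubic coefficients (time in hours since sunrise).
#' @param slope_night night slope, cm3 cm-3 h-1.
#' @param h daytime hour index, 1..floor(t_day).
#' @param thickness_mm layer thickness, mm.
#' @return Uptake, mm h-1 (vectorised).
#' @export
hourly_rwu_layer <- function(a, b, c, slope_night, h, thickness_mm) {
  t_h <- h - 0.5
  deriv <- a + 2 * b * t_h + 3 * c * t_h^2
  (slope_night - deriv) * thickness_mm
}

#' Hourly root water uptake per sensor layer
#'
#' @inheritParams rwu_daily
#' @param min_points_day minimum points for the daytime cubic (>= 8).
#' @param min_points_night minimum points for the night slope (>= 4).
#' @return Tibble per plot x date x hour x depth with `rwu_mm_h` and the
#'   hour's midpoint timestamp.
#' @export
rwu_hourly <- function(swc_clean, suntimes, scheme = layer_scheme(),
                       eligibility = NULL, min_points_day = 8L,
                       min_points_night = 4L) {
  seg <- segment_day_night(swc_clean, suntimes)
  polys <- fit_day_polynomials(seg, suntimes, min_points = min_points_day)
  nights <- seg |>
    filter(.data$phase == "night") |>
    fit_diel_slopes(min_points = min_points_night) |>
    select(-"phase") |>
    rename(slope_night = "slope", n_night = "n") |>
    select(-dplyr::any_of("resid_sd"))
  keys <- intersect(c("plot_id", "treatment", "depth_cm", "date"), names(polys))
  out <- polys |>
    inner_join(nights, by = keys) |>
    inner_join(suntimes[c("date", "sunrise", "t_day")], by = "date") |>
    filter(.data$t_day >= 1)
  out <- out |>
    mutate(hours = map(.data$t_day, ~seq_len(floor(.x)))) |>
    tidyr::unnest("hours") |>
    rename(hour = "hours") |>
    inner_join(scheme[c("depth_cm", "thickness_mm")], by = "depth_cm") |>
    mutate(
      rwu_mm_h = hourly_rwu_layer(.data$a, .data$b, .data$c,
                                  .data$slope_night, .data$hour,
                                  .data$thickness_mm),
      timestamp_mid = .data$sunrise + (.data$hour - 0.5) * 3600
    ) |>
    select(dplyr::all_of(keys), "date", "hour", "timestamp_mid", "n",
           "n_night", "rwu_mm_h", "thickness_mm") |>
    distinct()
  if (!is.null(eligibility)) {
    out <- out |>
      inner_join(eligibility[c("date", "eligible")], by = "date") |>
      filter(.data$eligible) |>
      select(-"eligible")
  }
  arrange(out, dplyr::pick(dplyr::all_of(c(setdiff(keys, "depth_cm"), "hour",
                                           "depth_cm"))))
}

#' Depth-weighted integration over the rooting horizon
#'
#' Sums per-layer uptake (already thickness-scaled to mm) over the layer
#' scheme to the 0-36 cm profile total and computes each layer's fraction
#' of the total. Profile records with any undefined layer are flagged
#' incomplete and get no total; fractions are defined only for positive
#' totals.
#'
#' @param layers per-layer tibble from [rwu_daily()] or [rwu_hourly()].
#' @param scheme the [layer_scheme()] the values were computed on.
#' @param value column name holding the layer value (auto-detected from
#'   `rwu_mm_day`/`rwu_mm_h` when `NULL`).
#' @return The input with `total`, `fraction` and `complete` columns added
#'   (total repeated within each profile).
#' @export
integrate_profile <- function(layers, scheme = layer_scheme(), value = NULL) {
  value <- value %||% intersect(c("rwu_mm_day", "rwu_mm_h"), names(layers))[1]
  if (is.na(value) || !value %in% names(layers)) {
    abort("cannot find the layer value column; pass `value`")
  }
  keys <- intersect(c("plot_id", "treatment", "date", "hour"), names(layers))
  keys <- setdiff(keys, "depth_cm")
  if (!all(layers$depth_cm %in% scheme$depth_cm)) {
    abort("layer values contain depths not present in the scheme")
  }
  layers |>
    group_by(dplyr::pick(dplyr::all_of(keys))) |>
    mutate(
      complete = sum(!is.na(.data[[value]])) == nrow(scheme),
      total = ifelse(.data$complete, sum(.data[[value]]), NA_real_),
      fraction = ifelse(!is.na(.data$total) & .data$total > 0,
                        .data[[value]] / .data$total, NA_real_)
    ) |>
    ungroup()
}

#' Maximum hourly uptake capacity per root layer
#'
#' For each hour with a complete profile in the window of `window_days`
#' days before `extraction_date`, per-sensor hourly uptake rates are
#' converted to per-mm-of-soil rates, linearly interpolated across sensor
#' depth to each root layer's midpoint (5, 15, 25 cm for 10-cm layers),
#' rescaled to the 100-mm root layer, and maximised over all hours in the
#' window — the realised uptake capacity the fine roots in that layer
#' supported.
#'
#' @param hourly per-layer hourly tibble from [rwu_hourly()].
#' @param extraction_date root extraction date (`Date`).
#' @param scheme the [layer_scheme()].
#' @param root_layer_mid_cm midpoints of the root layers, cm.
#' @param layer_thickness_mm thickness of each root layer, mm.
#' @param window_days days before extraction included (the window
#'   \[extraction - window_days, extraction - 1\]).
#' @return Tibble per plot x root layer: `layer_mid_cm`, `rwu_max_mm_h`,
#'   `n_hours`, window bounds. An empty window yields an undefined record
#'   (with a warning).
#' @export
rwu_max <- function(hourly, extraction_date, scheme = layer_scheme(),
                    root_layer_mid_cm = c(5, 15, 25),
                    layer_thickness_mm = 100, window_days = 10) {
  assert_cols(hourly, c("depth_cm", "date", "hour", "rwu_mm_h"), "hourly")
  extraction_date <- as.Date(extraction_date)
  win_lo <- extraction_date - window_days
  win_hi <- extraction_date - 1
  keys <- intersect(c("plot_id", "treatment"), names(hourly))
  win <- hourly |>
    filter(.data$date >= win_lo, .data$date <= win_hi) |>
    inner_join(scheme[c("depth_cm", "thickness_mm")],
               by = "depth_cm", suffix = c("", ".scheme"))
  layer_lab <- sprintf("%d-%d", root_layer_mid_cm - layer_thickness_mm / 20,
                       root_layer_mid_cm + layer_thickness_mm / 20)
  empty_record <- function(key_df) {
    tibble(layer = layer_lab, layer_mid_cm = root_layer_mid_cm,
           rwu_max_mm_h = NA_real_, n_hours = 0L,
           window_start = win_lo, window_end = win_hi)
  }
  if (nrow(win) == 0L) {
    warn(sprintf("no hourly profiles in the %d-day window before %s",
                 window_days, format(extraction_date)))
    return(empty_record())
  }
  grouped <- if (length(keys) > 0L) group_by(win, dplyr::pick(dplyr::all_of(keys))) else win
  out <- grouped |>
    group_modify(function(df, key) {
      prof <- df |>
        group_by(.data$date, .data$hour) |>
        filter(sum(!is.na(.data$rwu_mm_h)) == nrow(scheme)) |>
        ungroup()
      if (nrow(prof) == 0L) {
        warn("window holds no complete hourly profile")
        return(empty_record())
      }
      interp <- prof |>
        group_by(.data$date, .data$hour) |>
        group_modify(function(p, k) {
          rate_per_mm <- p$rwu_mm_h / p$thickness_mm
          y <- approx(p$depth_cm, rate_per_mm, xout = root_layer_mid_cm,
                      rule = 2)$y
          tibble(layer = layer_lab, layer_mid_cm = root_layer_mid_cm,
                 rwu_layer_mm_h = y * layer_thickness_mm)
        }) |>
        ungroup()
      interp |>
        group_by(.data$layer, .data$layer_mid_cm) |>
        summarise(
          rwu_max_mm_h = max(.data$rwu_layer_mm_h),
          n_hours = dplyr::n(), .groups = "drop"
        ) |>
        mutate(window_start = win_lo, window_end = win_hi)
    })
  ungroup(out)
}
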