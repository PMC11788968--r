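#' @title Soil-moisture quality control chain
#' @description
#' The cleaning chain for 15-min volumetric soil water content series
#' mirrors standard TDR-network practice: (1) remove values outside the
#' physical 0-0.6 cm3 cm-3 range, (2) smooth trends with centred hourly
#' medians, (3) fill short gaps by linear interpolation, (4) remove
#' remaining single-time-step spikes with a windowed robust z-score. Each
#' step flags every point it alters (`qc_flag` in
#' `ok`/`range_removed`/`gap_filled`/`spike_removed`/`missing`);
#' [clean_swc()] runs the whole chain in that order.
#' @name swc_qc
NULL

# Apply f per sensor series (plot_id x depth_cm when present), ordered in time.
per_sensor <- function(series, f) {
  keys <- intersect(c("plot_id", "depth_cm"), names(series))
  if (length(keys) == 0L) {
    return(f(arrange(series, .data$timestamp)))
  }
  series |>
    arrange(dplyr::pick(dplyr::all_of(keys)), .data$timestamp) |>
    group_by(dplyr::pick(dplyr::all_of(keys))) |>
    group_modify(function(df, key) f(df)) |>
    ungroup()
}

#' Remove physically impossible soil-moisture values
#'
#' Values outside the closed interval \[`lower`, `upper`\] (volumetric
#' limits, default 0-0.6 cm3 cm-3) are set missing and flagged
#' `range_removed`; in-range values are untouched. The bounds are treated
#' as a closed interval: a reading of exactly 0.6 is physically admissible
#' and retained.
#'
#' @param series tibble with `timestamp`, `swc` and (optionally) `qc_flag`.
#' @param lower,upper physical bounds, cm3 cm-3.
#' @return The series with out-of-range points set `NA` and flagged.
#' @examples
#' s <- tibble::tibble(timestamp = Sys.time() + 900 * (0:2),
#'                     swc = c(0.25, 0.61, 0.30))
#' range_filter(s)
#' @export
range_filter <- function(series, lower = 0, upper = 0.6) {
  assert_cols(series, c("timestamp", "swc"), "series")
  out <- as_tibble(series)
  if (!"qc_flag" %in% names(out)) out$qc_flag <- "ok"
  bad <- !is.na(out$swc) & (out$swc < lower | out$swc > upper)
  out$swc[bad] <- NA_real_
  out$qc_flag[bad] <- "range_removed"
  out$qc_flag[is.na(out$swc) & out$qc_flag == "ok"] <- "missing"
  out
}

#' Smooth soil-moisture trends with centred hourly medians
#'
#' Each retained point is replaced by the median of its centred one-hour
#' window (up to 5 points at 15-min resolution, +/- 2 steps), skipping
#' missing values. Missing points stay missing (gap treatment is
#' [fill_gaps()]'s job) and flags are unchanged: smoothing adjusts the
#' trend, it does not remove data.
#'
#' @param series tibble with `timestamp` and `swc` on a regular 15-min grid.
#' @param half_window_steps half-width of the median window in steps.
#' @return The smoothed series.
#' @export
smooth_hourly_median <- function(series, half_window_steps = 2L) {
  assert_cols(series, c("timestamp", "swc"), "series")
  per_sensor(as_tibble(series), function(df) {
    assert_regular_grid(df$timestamp, what = "swc")
    sm <- roll_stat(df$swc, half_window_steps, median)
    df$swc <- ifelse(is.na(df$swc), NA_real_, sm)
    df
  })
}

#' Fill short gaps by linear interpolation
#'
#' Missing runs no longer than `max_gap_h` hours are filled by linear
#' interpolation between the flanking valid points and flagged
#' `gap_filled`; longer runs (and series ends) are left missing. A fill
#' report is attached as the `"fill_report"` attribute (see
#' [fill_report()]).
#'
#' @param series tibble with `timestamp` and `swc` on a regular 15-min grid.
#' @param max_gap_h maximum gap length to fill, hours (> 0).
#' @return The filled series with a `"fill_report"` attribute.
#' @export
fill_gaps <- function(series, max_gap_h = 6) {
  assert_cols(series, c("timestamp", "swc"), "series")
  if (max_gap_h <= 0) abort("max_gap_h must be > 0")
  out <- per_sensor(as_tibble(series), function(df) {
    assert_regular_grid(df$timestamp, what = "swc")
    was_na <- is.na(df$swc)
    filled <- zoo::na.approx(df$swc, maxgap = round(max_gap_h * 4), na.rm = FALSE)
    if (!"qc_flag" %in% names(df)) df$qc_flag <- ifelse(was_na, "missing", "ok")
    now_ok <- was_na & !is.na(filled)
    df$swc <- as.numeric(filled)
    df$qc_flag[now_ok] <- "gap_filled"
    df
  })
  n <- nrow(out)
  n_filled <- sum(out$qc_flag == "gap_filled")
  attr(out, "fill_report") <- tibble(
    n_points = n,
    n_missing_before = n_filled + sum(is.na(out$swc)),
    n_filled = n_filled,
    filled_fraction = if (n > 0) n_filled / n else NA_real_
  )
  out
}

#' Fill report of a gap-filled series
#'
#' @param series output of [fill_gaps()] (or [clean_swc()]).
#' @return A one-row tibble: points, missing before filling, filled count
#'   and filled fraction of all points.
#' @export
fill_report <- function(series) {
  rep <- attr(series, "fill_report")
  if (is.null(rep)) abort("no fill report attached; run fill_gaps() first")
  rep
}

#' Remove single-time-step spikes
#'
#' A point is a spike when its deviation from the median of the surrounding
#' window exceeds `z_thresh` times the window's robust scale (MAD) while
#' neither neighbour does — the single-step criterion separating sensor
#' glitches (full recovery at the next step) from real wetting fronts,
#' which elevate consecutive points. Spikes are set missing and flagged
#' `spike_removed`. The operation is idempotent: removed points are missing
#' on a second pass and nothing further qualifies.
#'
#' @param series tibble with `timestamp` and `swc` on a regular 15-min grid.
#' @param z_thresh robust z-score threshold (> 0).
#' @param window_h full window width in hours (> 0).
#' @return The despiked series.
#' @export
detect_spikes <- function(series, z_thresh = 5, window_h = 4) {
  assert_cols(series, c("timestamp", "swc"), "series")
  if (z_thresh <= 0) abort("z_thresh must be > 0")
  if (window_h <= 0) abort("window_h must be > 0")
  half <- max(2L, round(window_h * 4 / 2))
  per_sensor(as_tibble(series), function(df) {
    assert_regular_grid(df$timestamp, what = "swc")
    x <- df$swc
    med <- roll_stat(x, half, median)
    scale <- roll_stat(x, half, function(w) stats::mad(w))
    dev <- abs(x - med)
    out <- !is.na(dev) & dev > z_thresh * scale
    out[is.na(out)] <- FALSE
    prev <- c(FALSE, out[-length(out)])
    nxt <- c(out[-1L], FALSE)
    spike <- out & !prev & !nxt
    if (!"qc_flag" %in% names(df)) df$qc_flag <- ifelse(is.na(x), "missing", "ok")
    df$swc[spike] <- NA_real_
    df$qc_flag[spike] <- "spike_removed"
    df
  })
}

#' Run the full soil-moisture cleaning chain
#'
#' Applies, in order, [range_filter()], [smooth_hourly_median()],
#' [fill_gaps()] and [detect_spikes()]. The order matters: physically
#' impossible values must not enter the medians, smoothing must precede
#' interpolation so gaps are bridged between trend values, and spike
#' removal is the final pass over what survives.
#'
#' @param series raw sensor tibble (`plot_id`, `depth_cm`, `timestamp`,
#'   `swc`, ...).
#' @param lower,upper physical range bounds.
#' @param max_gap_h maximum gap filled, hours.
#' @param z_thresh,window_h spike-detector settings.
#' @return Cleaned series with `qc_flag` set, a `"fill_report"` attribute
#'   and all retained values inside \[`lower`, `upper`\].
#' @examples
#' cfg <- scenario_config(n_days = 2, seed = 5)
#' sim <- simulate_soil_profile(generate_meteo(cfg), cfg)
#' noisy <- apply_sensor_model(sim$swc, cfg)$swc
#' cleaned <- clean_swc(noisy)
#' qc_summary(cleaned)
#' @export
clean_swc <- function(series, lower = 0, upper = 0.6, max_gap_h = 6,
                      z_thresh = 5, window_h = 4) {
  out <- series |>
    range_filter(lower = lower, upper = upper) |>
    smooth_hourly_median() |>
    fill_gaps(max_gap_h = max_gap_h)
  rep <- attr(out, "fill_report")
  out <- detect_spikes(out, z_thresh = z_thresh, window_h = window_h)
  attr(out, "fill_report") <- rep
  out
}

#' Count points per quality-control flag class
#'
#' @param series a cleaned series with a `qc_flag` column.
#' @return A tibble of flag counts and fractions.
#' @export
qc_summary <- function(series) {
  assert_cols(series, "qc_flag", "series")
  series |>
    group_by(qc_flag = factor(.data$qc_flag, levels = qc_levels)) |>
    summarise(n = dplyr::n(), .groups = "drop") |>
    tidyr::complete(.data$qc_flag, fill = list(n = 0L)) |>
    mutate(fraction = .data$n / sum(.data$n))
}
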