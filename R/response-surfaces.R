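#' Join hourly uptake with profile-mean soil moisture and VPD
#'
#' Builds the hourly analysis records behind the response surfaces: for
#' each complete hourly profile on an eligible day, the depth-integrated
#' uptake total is paired with the storage-weighted (thickness-weighted)
#' profile-mean soil water content and the mean VPD over that hour.
#'
#' @param hourly_profiles output of [integrate_profile()] on
#'   [rwu_hourly()] layers.
#' @param swc_clean cleaned soil-moisture series.
#' @param meteo meteorology tibble (`timestamp`, `vpd`).
#' @param eligibility optional [eligible_days()] table; ineligible days are
#'   dropped.
#' @param scheme the [layer_scheme()] used for the storage weighting.
#' @return Tibble per plot x date x hour: `timestamp_mid`, `rwu_mm_h`
#'   (profile total), `swc_mean` (cm3 cm-3), `vpd` (kPa). Disjoint inputs
#'   yield an empty tibble with a warning.
#' @export
build_hourly_join <- function(hourly_profiles, swc_clean, meteo,
                              eligibility = NULL, scheme = layer_scheme()) {
  assert_cols(hourly_profiles, c("date", "hour", "timestamp_mid", "total"),
              "hourly profiles")
  assert_cols(meteo, c("timestamp", "vpd"), "meteo")
  keys <- intersect(c("plot_id", "treatment"), names(hourly_profiles))
  totals <- hourly_profiles |>
    filter(.data$complete) |>
    distinct(dplyr::pick(dplyr::all_of(c(keys, "date", "hour", "timestamp_mid",
                                         "total")))) |>
    rename(rwu_mm_h = "total")

  swc_keys <- intersect(c("plot_id", "treatment"), names(swc_clean))
  profile_swc <- swc_clean |>
    inner_join(scheme[c("depth_cm", "thickness_mm")], by = "depth_cm",
               suffix = c("", ".scheme")) |>
    group_by(dplyr::pick(dplyr::all_of(c(swc_keys, "timestamp")))) |>
    summarise(
      swc_profile = if (any(is.na(.data$swc))) NA_real_ else
        sum(.data$swc * .data$thickness_mm) / sum(.data$thickness_mm),
      .groups = "drop"
    )

  hour_means <- function(ts_mid, values_ts, values) {
    lo <- ts_mid - 1800
    hi <- ts_mid + 1800
    vapply(seq_along(ts_mid), function(i) {
      sel <- values_ts >= lo[i] & values_ts < hi[i]
      if (!any(sel)) return(NA_real_)
      mean(values[sel], na.rm = TRUE)
    }, numeric(1))
  }

  out <- totals |>
    group_by(dplyr::pick(dplyr::all_of(keys))) |>
    group_modify(function(df, key) {
      psw <- profile_swc
      for (k in intersect(names(key), names(psw))) {
        psw <- psw[psw[[k]] == key[[k]], ]
      }
      df$swc_mean <- hour_means(df$timestamp_mid, psw$timestamp, psw$swc_profile)
      df$vpd <- hour_means(df$timestamp_mid, meteo$timestamp, meteo$vpd)
      df
    }) |>
    ungroup() |>
    filter(!is.na(.data$swc_mean), !is.na(.data$vpd), !is.na(.data$rwu_mm_h))
  if (!is.null(eligibility)) {
    out <- out |>
      inner_join(eligibility[c("date", "eligible")], by = "date") |>
      filter(.data$eligible) |>
      select(-"eligible")
  }
  if (nrow(out) == 0L) {
    warn("hourly profiles, soil moisture and meteorology share no timestamps")
  }
  out
}

#' Decile binning of a sample
#'
#' Bin edges sit at the 10%..90% sample quantiles; assignment uses stable
#' rank order (ties broken by position), so bin populations differ by at
#' most one when values are distinct. A sample with a single distinct value
#' collapses to one degenerate bin, flagged.
#'
#' @param values numeric vector with at least 10 finite values.
#' @param n_bins number of quantile bins (10 = deciles).
#' @return A list: `bin` (integer assignment, `NA` for non-finite values),
#'   `edges` (length `n_bins + 1`, min/quantiles/max), `degenerate`.
#' @examples
#' bin_deciles(1:100)$edges
#' @export
bin_deciles <- function(values, n_bins = 10L) {
  finite <- is.finite(values)
  x <- values[finite]
  if (length(x) < n_bins) {
    abort(sprintf("need at least %d finite values to form %d bins",
                  n_bins, n_bins))
  }
  bin <- rep(NA_integer_, length(values))
  if (length(unique(x)) == 1L) {
    bin[finite] <- 1L
    return(list(bin = bin, edges = rep(x[1L], 2L), degenerate = TRUE))
  }
  r <- rank(x, ties.method = "first")
  bin[finite] <- as.integer(ceiling(n_bins * r / length(x)))
  edges <- c(min(x), unname(quantile(x, probs = seq_len(n_bins - 1L) / n_bins)),
             max(x))
  list(bin = bin, edges = edges, degenerate = FALSE)
}

#' Decile-binned uptake-ratio response table
#'
#' The crossed design of the response analysis: per-record ratios are
#' computed first, then averaged within deciles of the *other* driver.
#' `binning = "vpd"` bins by VPD deciles and averages RWU/SWC (the
#' fraction of stored soil water extracted per hour); `binning = "swc"`
#' bins by SWC deciles and averages RWU/VPD (a canopy-conductance proxy,
#' mm h-1 kPa-1). Records with a zero denominator are excluded. 95%
#' confidence intervals use the normal approximation within bins.
#'
#' @param join output of [build_hourly_join()].
#' @param binning which driver defines the deciles.
#' @param group_cols optional extra grouping columns (e.g. `"treatment"`):
#'   deciles are computed pooled over all records, means per group within
#'   each bin.
#' @return A `decile_table` tibble: bin index, edges, n, `mean_ratio`,
#'   `ci_half`.
#' @export
ratio_table <- function(join, binning = c("vpd", "swc"), group_cols = NULL) {
  binning <- match.arg(binning)
  assert_cols(join, c("rwu_mm_h", "swc_mean", "vpd"), "hourly join")
  denom_col <- if (binning == "vpd") "swc_mean" else "vpd"
  bin_col <- if (binning == "vpd") "vpd" else "swc_mean"
  dat <- filter(join, .data[[denom_col]] > 0)
  if (nrow(dat) == 0L) abort("all denominator values are zero")
  b <- bin_deciles(dat[[bin_col]])
  dat$bin <- b$bin
  dat$ratio <- dat$rwu_mm_h / dat[[denom_col]]
  out <- dat |>
    group_by(dplyr::pick(dplyr::all_of(c("bin", group_cols)))) |>
    summarise(
      n = dplyr::n(),
      mean_ratio = mean(.data$ratio),
      ci_half = 1.96 * sd(.data$ratio) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    mutate(
      bin_lo = b$edges[pmin(.data$bin, length(b$edges) - 1L)],
      bin_hi = b$edges[pmin(.data$bin + 1L, length(b$edges))]
    ) |>
    select("bin", "bin_lo", "bin_hi", dplyr::all_of(group_cols), "n",
           "mean_ratio", "ci_half")
  structure(out,
            class = c("decile_table", class(out)),
            binning = binning,
            ratio = if (binning == "vpd") "rwu_swc" else "rwu_vpd",
            degenerate = b$degenerate)
}

#' Diel uptake-VPD hysteresis metrics
#'
#' Treats one day's hourly (VPD, RWU) sequence as a closed polygon in time
#' order and computes the shoelace signed area (mm h-1 kPa): zero area
#' means uptake retraces the same VPD path morning and afternoon
#' (degenerate loop); a nonzero area quantifies the hysteresis, with the
#' sign giving the loop's orientation. The peak lag is the hour of maximum
#' uptake minus the hour of maximum VPD.
#'
#' @param join output of [build_hourly_join()]; metrics are computed per
#'   plot x date when those columns are present.
#' @param eps area magnitudes below this count as degenerate.
#' @return Tibble per group: `n`, `area`, `orientation` in
#'   `{clockwise, counterclockwise, degenerate}`, `peak_lag_h`.
#' @export
hysteresis_metrics <- function(join, eps = 1e-12) {
  assert_cols(join, c("hour", "vpd", "rwu_mm_h"), "hourly join")
  keys <- intersect(c("plot_id", "treatment", "date"), names(join))
  one_day <- function(df) {
    df <- arrange(df, .data$hour)
    n <- nrow(df)
    if (n < 4L) {
      return(tibble(n = n, area = NA_real_, orientation = "degenerate",
                    peak_lag_h = NA_real_))
    }
    a <- shoelace_area(df$vpd, df$rwu_mm_h)
    tibble(
      n = n,
      area = a,
      orientation = if (abs(a) < eps) "degenerate"
        else if (a > 0) "counterclockwise" else "clockwise",
      peak_lag_h = df$hour[which.max(df$rwu_mm_h)] - df$hour[which.max(df$vpd)]
    )
  }
  if (length(keys) == 0L) return(one_day(join))
  join |>
    group_by(dplyr::pick(dplyr::all_of(keys))) |>
    group_modify(function(df, key) one_day(df)) |>
    ungroup()
}

# Signed area of the closed polygon (x, y) in vertex order (shoelace).
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}
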