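#' Plot daily uptake by soil layer
#'
#' Stacked per-layer daily root water uptake over time; layers are labelled
#' by sensor depth. Incomplete profile days are dropped.
#'
#' @param profile output of [integrate_profile()] on [rwu_daily()] layers.
#' @return A ggplot object.
#' @export
plot_rwu_profile <- function(profile) {
  assert_cols(profile, c("date", "depth_cm", "rwu_mm_day"), "profile")
  dat <- filter(profile, .data$complete)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$date, y = .data$rwu_mm_day,
    fill = factor(.data$depth_cm)
  )) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(x = NULL, y = "RWU (mm day⁻¹)",
                  fill = "Sensor depth (cm)") +
    ggplot2::theme_minimal()
}

#' Plot a decile response table
#'
#' Bin means with their 95% confidence intervals against the bin midpoint
#' of the binning driver (VPD for RWU/SWC, SWC for RWU/VPD).
#'
#' @param object a `decile_table` from [ratio_table()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.decile_table <- function(object, ...) {
  binning <- attr(object, "binning")
  ratio <- attr(object, "ratio")
  xlab <- if (binning == "vpd") "VPD decile midpoint (kPa)" else
    "SWC decile midpoint (cm³ cm⁻³)"
  ylab <- if (ratio == "rwu_swc") "RWU/SWC (mm h⁻¹ per cm³ cm⁻³)" else
    "RWU/VPD (mm h⁻¹ kPa⁻¹)"
  dat <- mutate(as_tibble(object), mid = (.data$bin_lo + .data$bin_hi) / 2)
  grp <- intersect("treatment", names(dat))
  aes <- if (length(grp) == 1L) {
    ggplot2::aes(x = .data$mid, y = .data$mean_ratio,
                 colour = .data$treatment)
  } else {
    ggplot2::aes(x = .data$mid, y = .data$mean_ratio)
  }
  ggplot2::ggplot(dat, aes) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_ratio - .data$ci_half,
      ymax = .data$mean_ratio + .data$ci_half
    )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot diel uptake-VPD hysteresis loops
#'
#' Each day's hourly (VPD, RWU) path drawn in time order; an open loop
#' shows uptake lagging VPD between the morning rise and afternoon fall.
#'
#' @param join output of [build_hourly_join()].
#' @param dates optional subset of dates to draw.
#' @return A ggplot object.
#' @export
plot_hysteresis <- function(join, dates = NULL) {
  assert_cols(join, c("date", "hour", "vpd", "rwu_mm_h"), "join")
  dat <- if (is.null(dates)) join else filter(join, .data$date %in% as.Date(dates))
  ggplot2::ggplot(arrange(dat, .data$date, .data$hour),
                  ggplot2::aes(x = .data$vpd, y = .data$rwu_mm_h,
                               colour = .data$hour, group = .data$date)) +
    ggplot2::geom_path(arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::facet_wrap(ggplot2::vars(.data$date)) +
    ggplot2::labs(x = "VPD (kPa)", y = "RWU (mm h⁻¹)",
                  colour = "Hour") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
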