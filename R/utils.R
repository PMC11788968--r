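#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join lag lead n bind_rows distinct across rename
#'   row_number group_modify
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map2 pmap list_rbind
#' @importFrom stats median mad quantile lm coef approx rnorm runif rbinom
#'   rexp sd setNames complete.cases
NULL

# Site defaults: ClimGrass-like montane grassland site in Styria, Austria.
SITE_LAT <- 47.496
SITE_LON <- 14.098
SITE_TZ <- "Etc/GMT-1"

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Rolling window statistic skipping missing values
#'
#' Applies `fun` to a centred window of `half * 2 + 1` points around each
#' index, dropping `NA`s. Windows are truncated at the series ends. Returns
#' `NA` where the window holds no finite value.
#'
#' @param x numeric vector.
#' @param half half-width of the window in steps.
#' @param fun summary function taking a numeric vector.
#' @return numeric vector of the same length as `x`.
#' @keywords internal
#' @noRd
roll_stat <- function(x, half, fun) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  idx <- seq_len(n)
  vapply(idx, function(i) {
    w <- x[max(1L, i - half):min(n, i + half)]
    w <- w[!is.na(w)]
    if (length(w) == 0L) NA_real_ else fun(w)
  }, numeric(1))
}

# Regular 15-min grid check; steps in minutes.
assert_regular_grid <- function(timestamp, step_min = 15, what = "series") {
  if (length(timestamp) < 2L) return(invisible(TRUE))
  d <- diff(as.numeric(timestamp)) / 60
  if (any(abs(d - step_min) > 1e-6)) {
    abort(sprintf("%s timestamps are not on a regular %d-min grid", what, step_min))
  }
  invisible(TRUE)
}

assert_cols <- function(df, cols, what = "data") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

# Site-local calendar date of a timestamp.
local_date <- function(timestamp) {
  as.Date(format(timestamp, "%Y-%m-%d"))
}

qc_levels <- c("ok", "range_removed", "gap_filled", "spike_removed", "missing")
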