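# Shared simulated fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Default ambient scenario with its estimation products.
ambient_run <- function() {
  cached("ambient", function() {
    cfg <- scenario_config(n_days = 30, seed = 101)
    met <- generate_meteo(cfg)
    sim <- simulate_soil_profile(met, cfg)
    elig <- eligible_days(met, window = "both", suntimes = sim$suntimes)
    list(cfg = cfg, met = met, sim = sim, elig = elig)
  })
}

# Integer-hour sun-times table for a span of dates (tiles the day exactly
# with the hourly grid).
flat_suntimes <- function(dates, sunrise = "05:00", sunset = "19:00") {
  compute_sun_times(dates, table = data.frame(
    date = dates, sunrise = sunrise, sunset = sunset
  ))
}

# A small clean sensor series on the 15-min grid.
grid_series <- function(swc, start = "2020-06-01 00:00:00") {
  tibble::tibble(
    timestamp = as.POSIXct(start, tz = "Etc/GMT-1") + 900 * (seq_along(swc) - 1),
    swc = swc
  )
}
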