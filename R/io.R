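TIMESTAMP_FMT <- "%Y-%m-%dT%H:%M:%S"

#' Read a long-format soil-moisture CSV
#'
#' Expects one observation per row with columns `plot_id`, `treatment`,
#' `depth_cm`, `timestamp` (ISO-8601, site-local), `swc` and optionally
#' `qc_flag`. Malformed timestamps and duplicate (plot, depth, timestamp)
#' keys are reported with their line numbers.
#'
#' @param path CSV path.
#' @param tz timezone the timestamps are interpreted in.
#' @return A soil-moisture tibble.
#' @export
read_swc_csv <- function(path, tz = SITE_TZ) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      plot_id = readr::col_character(),
      treatment = readr::col_character(),
      depth_cm = readr::col_double(),
      timestamp = readr::col_datetime(format = TIMESTAMP_FMT),
      swc = readr::col_double(),
      qc_flag = readr::col_character(),
      .default = readr::col_guess()
    ),
    locale = readr::locale(tz = tz),
    progress = FALSE
  )
  assert_cols(out, c("plot_id", "depth_cm", "timestamp", "swc"),
              sprintf("'%s'", path))
  probs <- readr::problems(out)
  if (nrow(probs) > 0L) {
    abort(sprintf("unparseable value(s) in %s at line(s) %s", path,
                  paste(utils::head(probs$row + 1L, 5L), collapse = ", ")))
  }
  if (anyNA(out$timestamp)) {
    abort(sprintf("unparseable timestamp(s) in %s at line(s) %s", path,
                  paste(utils::head(which(is.na(out$timestamp)) + 1L, 5L),
                        collapse = ", ")))
  }
  dup <- duplicated(out[c("plot_id", "depth_cm", "timestamp")])
  if (any(dup)) {
    abort(sprintf("duplicate (plot_id, depth_cm, timestamp) key(s) in %s at line(s) %s",
                  path, paste(utils::head(which(dup) + 1L, 5L), collapse = ", ")))
  }
  if (!"qc_flag" %in% names(out)) out$qc_flag <- "ok"
  out
}

#' Write a soil-moisture series as long-format CSV
#'
#' Locale-independent output: point decimal, ISO-8601 site-local
#' timestamps. Reading the file back with [read_swc_csv()] reproduces the
#' values and flags.
#'
#' @param series soil-moisture tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_swc_csv <- function(series, path) {
  assert_cols(series, c("plot_id", "depth_cm", "timestamp", "swc"), "series")
  out <- mutate(series, timestamp = format(.data$timestamp, TIMESTAMP_FMT))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write a meteorology CSV
#'
#' Columns: `timestamp` (ISO-8601, site-local), `air_temp`, `rel_humidity`,
#' `vpd`, `precip`.
#'
#' @param path CSV path.
#' @param tz timezone for reading.
#' @return A meteorology tibble ([read_meteo_csv()]) or the path,
#'   invisibly ([write_meteo_csv()]).
#' @export
read_meteo_csv <- function(path, tz = SITE_TZ) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      timestamp = readr::col_datetime(format = TIMESTAMP_FMT),
      .default = readr::col_double()
    ),
    locale = readr::locale(tz = tz),
    progress = FALSE
  )
  assert_cols(out, c("timestamp", "air_temp", "rel_humidity", "vpd", "precip"),
              sprintf("'%s'", path))
  if (anyNA(out$timestamp)) abort(sprintf("unparseable timestamp(s) in %s", path))
  out
}

#' @rdname read_meteo_csv
#' @param meteo meteorology tibble.
#' @export
write_meteo_csv <- function(meteo, path) {
  out <- mutate(meteo, timestamp = format(.data$timestamp, TIMESTAMP_FMT))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read or write a site configuration file
#'
#' The site configuration is a YAML key-value file holding coordinates,
#' timezone, sensor depths, cut dates, QC thresholds, eligibility rules and
#' the seed. Unknown keys are rejected with a message so typos cannot
#' silently change an analysis.
#'
#' @param path YAML path.
#' @return A validated named list of class `site_config`.
#' @export
read_site_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  validate_site_config(yaml::read_yaml(path))
}

#' @rdname read_site_config
#' @param config a site-config list.
#' @export
write_site_config <- function(config, path) {
  yaml::write_yaml(unclass(validate_site_config(config)), path)
  invisible(path)
}

#' @rdname read_site_config
#' @export
validate_site_config <- function(config) {
  known <- c("latitude", "longitude", "tz", "sensor_depths", "cut_dates",
             "snow_free_date", "rain_mm", "post_cut_days", "canopy_dev_days",
             "max_gap_h", "z_thresh", "window_h", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown site-config key(s): %s (known: %s)",
                  paste(unknown, collapse = ", "), paste(known, collapse = ", ")))
  }
  defaults <- list(latitude = SITE_LAT, longitude = SITE_LON, tz = SITE_TZ,
                   sensor_depths = c(3, 9, 18, 36), cut_dates = NULL,
                   snow_free_date = NULL, rain_mm = 2, post_cut_days = 14,
                   canopy_dev_days = 21, max_gap_h = 6, z_thresh = 5,
                   window_h = 4, seed = 1L)
  structure(utils::modifyList(defaults, config), class = "site_config")
}

#' Run the full estimation pipeline on a simulated scenario
#'
#' Executes the stages in dependency order — simulate, clean, windows,
#' daily and hourly uptake, decile response tables, hysteresis, root traits
#' — writing each stage's long-format CSV into `out_dir` together with a
#' run manifest (JSON: package version, configuration hash, output
#' checksums, per-stage record counts, collected warnings). Runs are
#' deterministic in the scenario seed: rerunning with an identical
#' configuration reproduces every output byte for byte.
#'
#' @param scenario a [scenario_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of
#'   `c("simulate", "clean", "windows", "rwu_daily", "rwu_hourly",
#'   "deciles", "hysteresis", "traits")`; dependencies must be included or
#'   already present as files in `out_dir`.
#' @param site optional [validate_site_config()] list for eligibility/QC
#'   settings.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(scenario = scenario_config(), out_dir,
                         stages = c("simulate", "clean", "windows",
                                    "rwu_daily", "rwu_hourly", "deciles",
                                    "hysteresis", "traits"),
                         site = validate_site_config(list())) {
  all_stages <- c("simulate", "clean", "windows", "rwu_daily", "rwu_hourly",
                  "deciles", "hysteresis", "traits")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  warnings <- character(0)
  counts <- list()
  scheme <- scenario$scheme

  need <- function(obj, file, reader, stage, dep) {
    if (!is.null(obj)) return(obj)
    if (file.exists(path(file))) return(reader(path(file)))
    abort(sprintf("stage '%s' needs '%s' from stage '%s'; include that stage or provide %s",
                  stage, file, dep, path(file)))
  }
  run <- function(code) {
    withCallingHandlers(code, warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  meteo <- swc_raw <- swc_clean <- elig <- suntimes <- daily <- hourly <- NULL
  if ("simulate" %in% stages) {
    meteo <- run(generate_meteo(scenario))
    sim <- run(simulate_soil_profile(meteo, scenario))
    corrupted <- run(apply_sensor_model(sim$swc, scenario))
    swc_raw <- corrupted$swc
    suntimes <- sim$suntimes
    write_meteo_csv(meteo, path("meteo.csv"))
    write_swc_csv(swc_raw, path("swc_raw.csv"))
    readr::write_csv(
      mutate(sim$truth, timestamp = format(.data$timestamp, TIMESTAMP_FMT)),
      path("truth.csv"), progress = FALSE)
    readr::write_csv(sim$daily_truth, path("truth_daily.csv"), progress = FALSE)
    cores <- run(generate_root_cores(scenario))
    readr::write_csv(cores, path("root_cores.csv"), progress = FALSE)
    counts$simulate <- nrow(swc_raw)
  }
  if ("clean" %in% stages) {
    swc_raw <- need(swc_raw, "swc_raw.csv", read_swc_csv, "clean", "simulate")
    swc_clean <- run(clean_swc(swc_raw, max_gap_h = site$max_gap_h,
                               z_thresh = site$z_thresh,
                               window_h = site$window_h))
    write_swc_csv(swc_clean, path("swc_clean.csv"))
    readr::write_csv(qc_summary(swc_clean), path("qc_summary.csv"),
                     progress = FALSE)
    counts$clean <- nrow(swc_clean)
  }
  if ("windows" %in% stages) {
    meteo <- need(meteo, "meteo.csv", read_meteo_csv, "windows", "simulate")
    if (is.null(suntimes)) {
      suntimes <- compute_sun_times(sort(unique(local_date(meteo$timestamp))),
                                    site$latitude, site$longitude, site$tz)
    }
    elig <- run(eligible_days(meteo, cut_dates = site$cut_dates,
                              snow_free_date = site$snow_free_date,
                              rain_mm = site$rain_mm,
                              post_cut_days = site$post_cut_days,
                              canopy_dev_days = site$canopy_dev_days))
    readr::write_csv(elig, path("eligibility.csv"), progress = FALSE)
    readr::write_csv(
      mutate(suntimes, sunrise = format(.data$sunrise, TIMESTAMP_FMT),
             sunset = format(.data$sunset, TIMESTAMP_FMT)),
      path("suntimes.csv"), progress = FALSE)
    counts$windows <- nrow(elig)
  }
  if ("rwu_daily" %in% stages) {
    swc_clean <- need(swc_clean, "swc_clean.csv", read_swc_csv, "rwu_daily", "clean")
    if (is.null(elig) || is.null(suntimes)) {
      abort("stage 'rwu_daily' needs stage 'windows'")
    }
    daily <- run(integrate_profile(
      rwu_daily(swc_clean, suntimes, scheme, eligibility = elig), scheme))
    readr::write_csv(daily, path("rwu_daily.csv"), progress = FALSE)
    counts$rwu_daily <- nrow(daily)
  }
  if ("rwu_hourly" %in% stages) {
    swc_clean <- need(swc_clean, "swc_clean.csv", read_swc_csv, "rwu_hourly", "clean")
    if (is.null(elig) || is.null(suntimes)) {
      abort("stage 'rwu_hourly' needs stage 'windows'")
    }
    hourly <- run(integrate_profile(
      rwu_hourly(swc_clean, suntimes, scheme, eligibility = elig), scheme))
    readr::write_csv(
      mutate(hourly, timestamp_mid = format(.data$timestamp_mid, TIMESTAMP_FMT)),
      path("rwu_hourly.csv"), progress = FALSE)
    counts$rwu_hourly <- nrow(hourly)
  }
  join <- NULL
  if (any(c("deciles", "hysteresis") %in% stages)) {
    if (is.null(hourly) || is.null(swc_clean) || is.null(meteo)) {
      abort("stages 'deciles'/'hysteresis' need stages 'rwu_hourly', 'clean' and 'windows'")
    }
    join <- run(build_hourly_join(hourly, swc_clean, meteo,
                                  eligibility = elig, scheme = scheme))
  }
  if ("deciles" %in% stages && nrow(join) >= 10L) {
    readr::write_csv(ratio_table(join, "vpd"), path("deciles_rwu_swc.csv"),
                     progress = FALSE)
    readr::write_csv(ratio_table(join, "swc"), path("deciles_rwu_vpd.csv"),
                     progress = FALSE)
    counts$deciles <- nrow(join)
  }
  if ("hysteresis" %in% stages && nrow(join) > 0L) {
    hm <- run(hysteresis_metrics(join))
    readr::write_csv(hm, path("hysteresis.csv"), progress = FALSE)
    counts$hysteresis <- nrow(hm)
  }
  if ("traits" %in% stages) {
    cores_path <- path("root_cores.csv")
    cores <- if (file.exists(cores_path)) {
      readr::read_csv(cores_path, show_col_types = FALSE, progress = FALSE)
    } else {
      run(generate_root_cores(scenario))
    }
    traits <- run(root_traits(cores))
    readr::write_csv(traits, path("traits.csv"), progress = FALSE)
    counts$traits <- nrow(traits)
  }

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(
    rapply(unclass(scenario), as.character, how = "replace"), cfg_file)
  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    tool = "rwudiel",
    version = as.character(utils::packageVersion("rwudiel")),
    config_hash = unname(tools::md5sum(cfg_file)),
    stages = stages,
    outputs = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, outputs))), outputs)),
    record_counts = counts,
    warnings = warnings
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  unlink(cfg_file)
  invisible(manifest)
}
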