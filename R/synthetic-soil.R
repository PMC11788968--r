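#' Forward-simulate multi-layer soil water with a known transpiration sink
#'
#' A layered bucket model on the 15-min meteorological grid, built so that
#' the diurnal slope estimator's two working assumptions hold by
#' construction: the transpiration sink acts only between sunrise and
#' sunset, and non-uptake vertical flow (linear drainage of water above
#' field capacity, plus an optional constant extra drainage term) operates
#' identically day and night.
#'
#' Per layer i and step: rain infiltrates top-down filling layers to field
#' capacity (excess percolates and ultimately leaves the profile); drainage
#' removes k (theta - theta_fc)+ per hour, routed into the layer below
#' (bottom outflow leaves the profile); during daytime a sink
#' S_i(t) = c(vpd) min(g vpd / (1 + vpd/vpd_sat), sink_max) beta(theta_i) f_i
#' (mm/h) extracts water: a Lohammar-type stomatal conductance response in
#' VPD capped by the energy-limited maximum rate (the midday plateau of
#' grassland transpiration), distributed over the root-profile weights f_i,
#' scaled by a linear soil-moisture stress ramp beta (0 at the wilting
#' point, 1 at the critical point wp + stress_frac (fc - wp)), and
#' down-regulated by the elevated-CO2 factor c whenever VPD exceeds the
#' configured threshold. Every booked flux is recorded, so water balance
#' closes to floating-point accuracy.
#'
#' @param meteo output of [generate_meteo()] covering the span.
#' @param config the [scenario_config()].
#' @param suntimes optional sun-times table (as from
#'   [compute_sun_times()], possibly user-supplied) defining the daytime
#'   window of the sink; computed astronomically from the config
#'   coordinates when `NULL`.
#' @return A list of class `soil_sim`:
#' \describe{
#'   \item{swc}{sensor-style tibble: `plot_id`, `treatment`, `depth_cm`,
#'     `timestamp`, `swc` (layer-mean, cm3 cm-3), `qc_flag = "ok"`.}
#'   \item{truth}{per-step, per-layer tibble: `timestamp`, `depth_cm`,
#'     `uptake_mm_h`, `drain_mm_h` (outflow from the layer).}
#'   \item{daily_truth}{`date`, `transpiration_mm` (sum of booked uptake).}
#'   \item{balance}{per-step profile fluxes: `precip_mm`,
#'     `infiltration_mm` (water entering storage), `drain_out_mm`
#'     (water leaving the profile).}
#'   \item{suntimes}{the sun-times table used for the daytime switch.}
#' }
#' @examples
#' cfg <- scenario_config(n_days = 3, seed = 2)
#' sim <- simulate_soil_profile(generate_meteo(cfg), cfg)
#' head(sim$daily_truth)
#' @export
simulate_soil_profile <- function(meteo, config, suntimes = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  assert_cols(meteo, c("timestamp", "vpd", "precip"), "meteo")
  assert_regular_grid(meteo$timestamp, what = "meteo")

  scheme <- config$scheme
  nl <- nrow(scheme)
  thick <- scheme$thickness_mm
  rf <- config$root_fraction
  so <- config$soil
  theta_crit <- so$wilting_point + so$stress_frac * (so$field_capacity - so$wilting_point)
  dt <- 0.25
  n <- nrow(meteo)

  dates <- sort(unique(local_date(meteo$timestamp)))
  if (is.null(suntimes)) {
    suntimes <- compute_sun_times(dates, config$latitude, config$longitude,
                                  config$tz)
  }
  st <- suntimes[match(local_date(meteo$timestamp), suntimes$date), ]
  is_day <- meteo$timestamp >= st$sunrise & meteo$timestamp < st$sunset

  theta <- rep_len(so$init_theta, nl)
  theta_out <- matrix(NA_real_, n, nl)
  uptake_out <- matrix(0, n, nl)
  drain_out_layer <- matrix(0, n, nl)
  infil_step <- numeric(n)
  drain_out_step <- numeric(n)

  # unstressed profile sink rate (mm/h): conductance response capped by the
  # energy-limited maximum, then the eCO2 down-regulation above threshold
  sink_pot <- pmin(config$sink_gain * meteo$vpd / (1 + meteo$vpd / config$vpd_sat),
                   config$sink_max) *
    ifelse(meteo$vpd > config$eco2_vpd_threshold, config$eco2_factor, 1)

  canopy_store <- 0 # mm held on the canopy (interception)
  canopy_cap <- config$meteo$interception_mm %||% 0

  for (s in seq_len(n)) {
    # daytime root-water-uptake sink
    if (is_day[s] && meteo$vpd[s] > 0) {
      beta <- clamp((theta - so$wilting_point) / (theta_crit - so$wilting_point), 0, 1)
      up_mm <- sink_pot[s] * beta * rf * dt
      up_mm <- pmin(up_mm, pmax(theta - so$wilting_point, 0) * thick)
      theta <- theta - up_mm / thick
      uptake_out[s, ] <- up_mm / dt
    }
    # linear drainage of water above field capacity, routed downward
    perc_mm <- so$drainage_k * pmax(theta - so$field_capacity, 0) * dt * thick
    theta <- theta - perc_mm / thick
    if (nl > 1L) theta[-1L] <- theta[-1L] + perc_mm[-nl] / thick[-1L]
    # constant extra vertical flow, straight out of each layer
    ex_mm <- pmin(so$extra_drainage * dt * thick, pmax(theta, 0) * thick)
    theta <- theta - ex_mm / thick
    drain_out_layer[s, ] <- (perc_mm + ex_mm) / dt
    # canopy interception: the first canopy_cap mm of an event wet the
    # canopy and later evaporate; only throughfall reaches the soil
    water <- meteo$precip[s]
    if (water > 0 && canopy_store < canopy_cap) {
      held <- min(water, canopy_cap - canopy_store)
      canopy_store <- canopy_store + held
      water <- water - held
    } else if (water == 0 && is_day[s] && canopy_store > 0) {
      canopy_store <- max(0, canopy_store - 0.4 * dt) # canopy dries by day
    }
    # infiltration: throughfall fills layers top-down to field capacity
    throughfall <- water
    if (water > 0) {
      for (i in seq_len(nl)) {
        room <- max(so$field_capacity - theta[i], 0) * thick[i]
        add <- min(water, room)
        theta[i] <- theta[i] + add / thick[i]
        water <- water - add
      }
    }
    # intercepted and pass-through rain never enter storage: neither is
    # infiltration into the profile nor drainage out of it
    infil_step[s] <- throughfall - water
    drain_out_step[s] <- perc_mm[nl] + sum(ex_mm)

    if (any(theta < -1e-9) || any(theta > so$porosity + 1e-9)) {
      abort(sprintf(
        "soil state left [0, porosity] at step %d (theta = %s); reduce fluxes or step size",
        s, paste(signif(theta, 4), collapse = ", ")
      ))
    }
    theta_out[s, ] <- theta
  }

  treatment <- paste(c(
    if (config$warming_offset > 0) "warming",
    if (config$eco2_factor < 1) "eco2",
    if (!is.null(config$drought)) "drought"
  ), collapse = "+")
  if (treatment == "") treatment <- "ambient"

  swc <- tidyr::expand_grid(
    depth_cm = scheme$depth_cm,
    timestamp = meteo$timestamp
  ) |>
    mutate(
      plot_id = "sim-1", treatment = treatment,
      swc = as.vector(theta_out),
      qc_flag = "ok"
    ) |>
    select("plot_id", "treatment", "depth_cm", "timestamp", "swc", "qc_flag")

  truth <- tidyr::expand_grid(
    depth_cm = scheme$depth_cm,
    timestamp = meteo$timestamp
  ) |>
    mutate(
      uptake_mm_h = as.vector(uptake_out),
      drain_mm_h = as.vector(drain_out_layer)
    ) |>
    select("timestamp", "depth_cm", "uptake_mm_h", "drain_mm_h")

  daily_truth <- tibble(
    date = local_date(meteo$timestamp),
    uptake_mm = rowSums(uptake_out) * dt
  ) |>
    group_by(.data$date) |>
    summarise(transpiration_mm = sum(.data$uptake_mm), .groups = "drop")

  balance <- tibble(
    timestamp = meteo$timestamp,
    precip_mm = meteo$precip,
    infiltration_mm = infil_step,
    drain_out_mm = drain_out_step
  )

  structure(
    list(swc = swc, truth = truth, daily_truth = daily_truth,
         balance = balance, suntimes = suntimes, config = config),
    class = "soil_sim"
  )
}

#' Inject sensor artefacts into a clean soil-moisture series
#'
#' Adds, per sensor (plot x depth), the artefact classes the quality-control
#' chain is built to remove: Gaussian measurement noise, single-step spikes
#' (a displacement much larger than the noise with full recovery at the next
#' step), gap runs (deleted values), and out-of-range excursions beyond the
#' physical 0-0.6 cm3 cm-3 limits. Injection positions are logged so QC
#' performance can be scored.
#'
#' @param truth_swc clean series (`plot_id`, `depth_cm`, `timestamp`, `swc`).
#' @param config a [scenario_config()]; rates come from `config$sensor` and
#'   randomness from `config$seed`.
#' @return A list with `swc` (the corrupted series) and `log` (tibble of
#'   injected artefacts: `plot_id`, `depth_cm`, `timestamp`, `kind` in
#'   `{spike, gap, out_of_range}`).
#' @export
apply_sensor_model <- function(truth_swc, config) {
  stopifnot(inherits(config, "scenario_config"))
  assert_cols(truth_swc, c("plot_id", "depth_cm", "timestamp", "swc"), "swc")
  sn <- config$sensor
  if (sn$noise_sd < 0) abort("sensor noise_sd must be >= 0")

  with_seed(config$seed + 1L, {
    out <- truth_swc |>
      arrange(.data$plot_id, .data$depth_cm, .data$timestamp) |>
      group_by(.data$plot_id, .data$depth_cm) |>
      group_modify(function(df, key) {
        n <- nrow(df)
        x <- df$swc + rnorm(n, 0, sn$noise_sd)
        kind <- rep(NA_character_, n)
        # single-step spikes (not at the series edges)
        sp <- which(runif(n) < sn$spike_prob)
        sp <- sp[sp > 1L & sp < n]
        if (length(sp) > 0L) {
          x[sp] <- x[sp] + sn$spike_mag * sample(c(-1, 1), length(sp), replace = TRUE)
          kind[sp] <- "spike"
        }
        # out-of-range excursions
        oor <- which(runif(n) < sn$oor_frac)
        if (length(oor) > 0L) {
          x[oor] <- ifelse(runif(length(oor)) < 0.5,
                           -runif(length(oor), 0.01, 0.2),
                           0.6 + runif(length(oor), 0.01, 0.2))
          kind[oor] <- "out_of_range"
        }
        # gap runs
        starts <- which(runif(n) < sn$gap_prob)
        for (g in starts) {
          len <- max(1L, round(rexp(1, 1 / sn$gap_mean_steps)))
          sel <- g:min(n, g + len - 1L)
          x[sel] <- NA_real_
          kind[sel] <- "gap"
        }
        df$swc <- x
        df$artefact <- kind
        df
      }) |>
      ungroup()
    log <- out |>
      filter(!is.na(.data$artefact)) |>
      select("plot_id", "depth_cm", "timestamp", kind = "artefact")
    swc <- out |>
      mutate(qc_flag = ifelse(is.na(.data$swc), "missing", "ok")) |>
      select(-"artefact")
    list(swc = swc, log = log)
  })
}

#' Generate synthetic ingrowth-core fine-root records
#'
#' Emulates the ingrowth-core sampling design (4 cm diameter cores, 30 cm
#' deep, split into 0-10/10-20/20-30 cm segments, extracted at each
#' grassland cut): per plot x period x layer, fine-root dry mass, specific
#' root length and mean diameter are drawn with log-normal noise around
#' treatment means (mass declining with depth), root length and projected
#' area follow from cylindrical geometry (area = length x diameter), and a
#' latent per-layer uptake capacity is generated with configured linear
#' couplings to mass density, SRL and diameter so recovery of those
#' couplings can be tested.
#'
#' @param config a [scenario_config()] (seed and treatment label).
#' @param n_plots,n_periods sampling design size.
#' @param mass_g mean fine-root dry mass (g) per core segment in the top
#'   layer.
#' @param layer_decay multiplicative decline of mass per 10-cm layer.
#' @param srl_m_g mean specific root length, m g-1.
#' @param diam_mm mean root diameter, mm.
#' @param noise_sd_log log-scale sd of the log-normal trait noise
#'   (0 = every record equals its treatment mean).
#' @param coupling list with `intercept` and slopes `mass_density`
#'   (per mg cm-3), `srl` (per m g-1), `diameter` (per mm) linking traits to
#'   the latent capacity `rwu_max_latent` (mm h-1), plus `noise_sd`.
#' @return A tibble of core records with internally consistent geometry and
#'   the latent capacity column.
#' @examples
#' cores <- generate_root_cores(scenario_config(seed = 3), n_plots = 4)
#' head(cores)
#' @export
generate_root_cores <- function(config,
                                n_plots = 8, n_periods = 3,
                                mass_g = 0.15, layer_decay = 0.5,
                                srl_m_g = 100, diam_mm = 0.4,
                                noise_sd_log = 0.25,
                                coupling = list(intercept = 0.02,
                                                mass_density = 0.05,
                                                srl = 5e-4,
                                                diameter = -0.05,
                                                noise_sd = 0.01)) {
  stopifnot(inherits(config, "scenario_config"))
  if (mass_g <= 0 || srl_m_g <= 0 || diam_mm <= 0) {
    abort("trait means must be positive")
  }
  layers <- tibble(
    layer = c("0-10", "10-20", "20-30"),
    layer_top_cm = c(0, 10, 20),
    mass_mean = mass_g * layer_decay^(0:2)
  )
  core_volume_cm3 <- pi * 2^2 * 10 # 4 cm diameter, 10 cm segment

  with_seed(config$seed + 2L, {
    grid <- tidyr::expand_grid(
      plot = sprintf("plot-%02d", seq_len(n_plots)),
      period = seq_len(n_periods),
      layers
    )
    nlog <- noise_sd_log
    draw <- function(mean) {
      if (nlog == 0) rep(mean, nrow(grid))
      else exp(rnorm(nrow(grid), log(mean) - nlog^2 / 2, nlog))
    }
    grid |>
      mutate(
        dry_mass_g = draw(1) * .data$mass_mean,
        srl = draw(srl_m_g),
        mean_diameter_mm = draw(diam_mm),
        total_length_m = .data$dry_mass_g * .data$srl,
        projected_area_m2 = .data$total_length_m * .data$mean_diameter_mm / 1000,
        root_mass_density_mg_cm3 = 1000 * .data$dry_mass_g / core_volume_cm3,
        rwu_max_latent = coupling$intercept +
          coupling$mass_density * .data$root_mass_density_mg_cm3 +
          coupling$srl * .data$srl +
          coupling$diameter * .data$mean_diameter_mm +
          rnorm(dplyr::n(), 0, coupling$noise_sd)
      ) |>
      select("plot", "period", "layer", "layer_top_cm", "dry_mass_g",
             "total_length_m", "projected_area_m2", "mean_diameter_mm",
             "root_mass_density_mg_cm3", "rwu_max_latent")
  })
}
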