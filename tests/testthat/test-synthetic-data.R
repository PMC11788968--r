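test_that("VPD follows the Magnus saturation curve", {
  # independent hand evaluation of es(25) = 0.6108 exp(17.27*25/262.3)
  es25 <- 0.6108 * exp(17.27 * 25 / (25 + 237.3))
  expect_equal(vpd_from_t_rh(25, 50), es25 * 0.5, tolerance = 1e-12)
  expect_identical(vpd_from_t_rh(20, 100), 0)
  expect_equal(vpd_from_t_rh(0, 0), 0.6108, tolerance = 1e-12)
  expect_error(vpd_from_t_rh(20, 101), "rel_humidity")
})

test_that("meteo generator honours saturation, drought windows and the seed", {
  cfg <- scenario_config(n_days = 4, seed = 10,
                         meteo = list(rh_mean = 100, rh_amp = 0, rh_day_sd = 0))
  met <- generate_meteo(cfg)
  expect_true(all(met$vpd == 0))

  cfg2 <- scenario_config(n_days = 25, seed = 10,
                          meteo = list(rain_prob = 0.9),
                          drought = list(start_day = 10, end_day = 20,
                                         rewet_mm = 40))
  met2 <- generate_meteo(cfg2)
  day_idx <- as.integer(as.Date(format(met2$timestamp, "%Y-%m-%d")) -
                          cfg2$start_date) + 1L
  in_window <- day_idx >= 10 & day_idx <= 20
  # all natural rain excluded; the only event is the single 40 mm rewetting
  # at noon of the end day
  expect_equal(sum(met2$precip[in_window]), 40)
  expect_equal(sum(met2$precip[in_window] > 0), 1L)
  expect_equal(unique(day_idx[in_window & met2$precip > 0]), 20L)

  expect_identical(generate_meteo(cfg2), generate_meteo(cfg2))
  expect_error(scenario_config(n_days = 0), "n_days")
  expect_error(scenario_config(n_days = 5,
                               drought = list(start_day = 3, end_day = 9)),
               "drought window")
})

test_that("soil simulator books no uptake without a sink and closes a one-flux balance", {
  cfg <- scenario_config(n_days = 3, seed = 11, sink_gain = 0,
                         meteo = list(rain_prob = 0))
  sim <- simulate_soil_profile(generate_meteo(cfg), cfg)
  expect_true(all(sim$truth$uptake_mm_h == 0))
  expect_equal(sim$daily_truth$transpiration_mm, rep(0, 3))

  # single layer, no drainage, no rain: daily theta drop x thickness equals
  # the booked transpiration exactly
  scheme1 <- layer_scheme(sensor_depth_cm = 18, horizon_cm = 36)
  cfg1 <- scenario_config(n_days = 2, seed = 12, root_fraction = 1,
                          scheme = scheme1,
                          meteo = list(rain_prob = 0),
                          soil = list(drainage_k = 0, init_theta = 0.30))
  sim1 <- simulate_soil_profile(generate_meteo(cfg1), cfg1)
  # theta at the first step (midnight, no flux) vs theta at the start of
  # the next day spans exactly day one's uptake
  drop_day_mm <- (sim1$swc$swc[1] - sim1$swc$swc[97]) * scheme1$thickness_mm
  expect_equal(drop_day_mm, sim1$daily_truth$transpiration_mm[1],
               tolerance = 1e-9)
})

test_that("simulator water balance closes over a default scenario", {
  run <- ambient_run()
  cfg <- run$cfg
  sim <- run$sim
  stor0 <- sum(cfg$soil$init_theta * cfg$scheme$thickness_mm)
  last <- sim$swc[sim$swc$timestamp == max(sim$swc$timestamp), ]
  stor1 <- sum(last$swc * cfg$scheme$thickness_mm)
  uptake <- sum(sim$truth$uptake_mm_h) * 0.25
  flux <- sum(sim$balance$infiltration_mm) - sum(sim$balance$drain_out_mm) -
    uptake
  expect_lt(abs((stor1 - stor0) - flux), 1e-6)
  # estimator assumption held by construction: no uptake outside daytime
  seg <- segment_day_night(sim$truth, sim$suntimes)
  expect_true(all(seg$uptake_mm_h[seg$phase == "night"] == 0))
})

test_that("drought dries the profile from the top down", {
  cfg <- scenario_config(n_days = 30, seed = 13,
                         drought = list(start_day = 5, end_day = 28,
                                        rewet_mm = 40))
  sim <- simulate_soil_profile(generate_meteo(cfg), cfg)
  swc <- sim$swc
  swc$date <- as.Date(format(swc$timestamp, "%Y-%m-%d"))
  daily <- aggregate(swc ~ date + depth_cm, swc, mean)
  wide <- reshape(daily, idvar = "date", timevar = "depth_cm",
                  direction = "wide")
  top_below <- wide$swc.3 < wide$swc.36
  # once the top layer is drier than the bottom it stays drier until rewetting
  first <- which(top_below)[1]
  expect_false(is.na(first))
  rewet_date <- cfg$start_date + 27
  expect_true(all(top_below[seq(first, sum(wide$date < rewet_date))]))
  # and the reverse never occurs before the top-down ordering appears
  if (first > 1) expect_false(any(wide$swc.36[1:(first - 1)] < wide$swc.3[1:(first - 1)] - 1e-12))
})

test_that("sensor model is the identity at zero rates and logs its injections", {
  run <- ambient_run()
  clean <- run$sim$swc
  cfg0 <- scenario_config(n_days = 30, seed = 101,
                          sensor = list(noise_sd = 0, spike_prob = 0,
                                        gap_prob = 0, oor_frac = 0))
  out0 <- apply_sensor_model(clean, cfg0)
  expect_equal(out0$swc$swc, clean$swc)
  expect_equal(nrow(out0$log), 0L)

  cfg1 <- scenario_config(n_days = 30, seed = 101,
                          sensor = list(noise_sd = 0, spike_prob = 0.002,
                                        gap_prob = 0, oor_frac = 0))
  out1 <- apply_sensor_model(clean, cfg1)
  n_spike <- sum(out1$log$kind == "spike")
  n_pts <- nrow(clean)
  expect_gt(n_spike, 0)
  # logged count matches actual displaced points exactly
  m <- merge(out1$swc, clean, by = c("plot_id", "depth_cm", "timestamp"))
  expect_equal(sum(abs(m$swc.x - m$swc.y) > 1e-12), n_spike)
  # expected count ~ p * N (binomial, allow 5 sd)
  expect_lt(abs(n_spike - 0.002 * n_pts), 5 * sqrt(0.002 * n_pts))

  cfg2 <- scenario_config(n_days = 30, seed = 101,
                          sensor = list(noise_sd = 0.002, spike_prob = 0,
                                        gap_prob = 0, oor_frac = 0))
  out2 <- apply_sensor_model(clean, cfg2)
  dev <- out2$swc$swc - clean$swc
  expect_gt(length(dev), 1e4)
  expect_lt(abs(sd(dev) - 0.002) / 0.002, 0.1)
})

test_that("root-core generator has consistent geometry and recoverable couplings", {
  cfg <- scenario_config(seed = 21)
  cores0 <- generate_root_cores(cfg, n_plots = 3, noise_sd_log = 0)
  # zero noise: every record equals its treatment mean
  expect_equal(unique(round(cores0$mean_diameter_mm, 12)), 0.4)
  expect_equal(unique(round(cores0$total_length_m / cores0$dry_mass_g, 9)), 100)
  top <- cores0[cores0$layer == "0-10", ]
  expect_equal(unique(round(top$dry_mass_g, 12)), 0.15)
  # projected area = length x diameter (cylindrical projection):
  # 20 m x 0.5 mm -> 0.01 m2
  expect_equal(unique(cores0$projected_area_m2 / cores0$total_length_m),
               0.4 / 1000)
  cores1 <- generate_root_cores(cfg, n_plots = 12)
  expect_equal(cores1$projected_area_m2,
               cores1$total_length_m * cores1$mean_diameter_mm / 1000)
  # OLS on the ensemble recovers the configured mass-density coupling
  fit <- lm(rwu_max_latent ~ root_mass_density_mg_cm3 + srl_fit + diam,
            data = transform(cores1,
                             srl_fit = total_length_m / dry_mass_g,
                             diam = mean_diameter_mm))
  est <- coef(summary(fit))["root_mass_density_mg_cm3", ]
  expect_lt(abs(est["Estimate"] - 0.05), 2 * est["Std. Error"])
  expect_error(generate_root_cores(cfg, mass_g = 0), "positive")
})
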