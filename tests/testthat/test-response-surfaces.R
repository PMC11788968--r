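test_that("storage-weighted profile mean and join counts match brute force", {
  scheme <- layer_scheme()
  # 60/75/135/90 mm weights on theta (0.2, 0.3, 0.3, 0.4):
  # (0.2*60 + 0.3*75 + 0.3*135 + 0.4*90) / 360 = 111/360
  w <- sum(c(0.2, 0.3, 0.3, 0.4) * scheme$thickness_mm) /
    sum(scheme$thickness_mm)
  expect_equal(w, 111 / 360)

  run <- ambient_run()
  cfg <- run$cfg
  hr <- integrate_profile(
    rwu_hourly(run$sim$swc, run$sim$suntimes, cfg$scheme,
               eligibility = run$elig), cfg$scheme)
  j <- build_hourly_join(hr, run$sim$swc, run$met, eligibility = run$elig,
                         scheme = cfg$scheme)
  expect_true(all(j$swc_mean >= 0 & j$swc_mean <= 0.6))
  # join size equals the number of complete eligible hourly profiles whose
  # hour window overlaps the met/swc grid (set-intersection oracle)
  complete_hours <- unique(hr[hr$complete, c("date", "hour")])
  elig_dates <- run$elig$date[run$elig$eligible]
  expect_equal(nrow(j),
               nrow(complete_hours[complete_hours$date %in% elig_dates, ]))

  # disjoint inputs: empty with a diagnostic
  met_far <- run$met
  met_far$timestamp <- met_far$timestamp + 400 * 86400
  swc_far <- run$sim$swc
  swc_far$timestamp <- swc_far$timestamp + 400 * 86400
  expect_warning(
    j0 <- build_hourly_join(hr, swc_far, met_far, scheme = cfg$scheme),
    "share no timestamps")
  expect_equal(nrow(j0), 0L)
})

test_that("decile binning matches a sort-and-slice oracle", {
  b <- bin_deciles(1:100)
  expect_equal(as.vector(table(b$bin)), rep(10L, 10))

  same <- bin_deciles(rep(2.5, 20))
  expect_true(same$degenerate)
  expect_equal(unique(same$bin), 1L)

  set.seed(11)
  x <- rnorm(437)
  b2 <- bin_deciles(x)
  # populations differ by at most one
  expect_lte(diff(range(table(b2$bin))), 1)
  # sort-and-slice oracle: element ranks decide bins
  ord <- order(x)
  oracle <- integer(length(x))
  oracle[ord] <- ceiling(10 * seq_along(x) / length(x))
  expect_equal(b2$bin, oracle)
  expect_error(bin_deciles(1:5), "at least")
})

test_that("ratio tables equal a group-by oracle and respect record order", {
  set.seed(12)
  n <- 300
  j <- tibble::tibble(
    rwu_mm_h = runif(n, 0, 0.4),
    swc_mean = runif(n, 0.15, 0.45),
    vpd = runif(n, 0.05, 3)
  )
  tab <- ratio_table(j, binning = "vpd")
  b <- bin_deciles(j$vpd)
  oracle <- tapply(j$rwu_mm_h / j$swc_mean, b$bin, mean)
  expect_equal(tab$mean_ratio, as.vector(oracle))
  expect_equal(sum(tab$n), n)

  # order invariance
  perm <- j[sample(n), ]
  tab2 <- ratio_table(perm, binning = "vpd")
  expect_equal(tab2$mean_ratio, tab$mean_ratio)

  # constant ratio: every bin mean identical with zero CI width
  jc <- tibble::tibble(rwu_mm_h = 0.2, swc_mean = 0.25,
                       vpd = seq(0.1, 3, length.out = 50))
  tabc <- ratio_table(jc, binning = "vpd")
  expect_true(all(abs(tabc$mean_ratio - 0.8) < 1e-12))
  expect_true(all(tabc$ci_half < 1e-12))

  # vpd = 0 records are excluded from the RWU/VPD table
  j0 <- j
  j0$vpd[1:20] <- 0
  tab0 <- ratio_table(j0, binning = "swc")
  expect_equal(sum(tab0$n), n - 20L)
})

test_that("hysteresis areas follow the shoelace formula", {
  # retraced path: degenerate
  v <- c(0.5, 1, 1.5, 2, 1.5, 1, 0.5, 0.2)
  r <- v * 0.1
  d1 <- hysteresis_metrics(tibble::tibble(hour = seq_along(v), vpd = v,
                                          rwu_mm_h = r))
  expect_equal(d1$orientation, "degenerate")
  expect_lt(abs(d1$area), 1e-12)

  # rectangle traversed once: |area| = width x height
  rect <- tibble::tibble(
    hour = 1:4,
    vpd = c(1, 3, 3, 1),
    rwu_mm_h = c(0.1, 0.1, 0.4, 0.4)
  )
  d2 <- hysteresis_metrics(rect)
  expect_equal(abs(d2$area), 2 * 0.3, tolerance = 1e-12)
  expect_equal(d2$orientation, "counterclockwise")
  d3 <- hysteresis_metrics(rect[c(1, 4, 3, 2), ] |>
                             dplyr::mutate(hour = 1:4))
  expect_equal(d3$orientation, "clockwise")

  # random loop vs an independent shoelace implementation
  set.seed(13)
  x <- runif(24); y <- runif(24)
  ours <- hysteresis_metrics(tibble::tibble(hour = 1:24, vpd = x,
                                            rwu_mm_h = y))$area
  n <- length(x)
  oracle <- 0
  for (i in seq_len(n)) {
    k <- if (i == n) 1L else i + 1L
    oracle <- oracle + (x[i] * y[k] - x[k] * y[i])
  }
  expect_equal(ours, oracle / 2, tolerance = 1e-12)
  # fewer than 4 hours: degenerate
  short <- hysteresis_metrics(tibble::tibble(hour = 1:3, vpd = 1:3,
                                             rwu_mm_h = 1:3))
  expect_equal(short$orientation, "degenerate")
})

test_that("drought makes roots extract a larger fraction of a smaller store", {
  # paired scenarios, identical weather seed, only the rain exclusion added
  mk <- function(drought) {
    # moist, regularly rewetted early summer: the ambient store stays high
    # while the excluded plots draw theirs down on the flat part of the
    # stress ramp
    cfg <- scenario_config(n_days = 30, seed = 51, drought = drought,
                           soil = list(init_theta = 0.40),
                           meteo = list(rain_prob = 0.5))
    met <- generate_meteo(cfg)
    sim <- simulate_soil_profile(met, cfg)
    elig <- eligible_days(met, window = "both", suntimes = sim$suntimes)
    hr <- integrate_profile(
      rwu_hourly(sim$swc, sim$suntimes, cfg$scheme, eligibility = elig),
      cfg$scheme)
    j <- build_hourly_join(hr, sim$swc, met, eligibility = elig,
                           scheme = cfg$scheme)
    j$rwu_swc <- j$rwu_mm_h / j$swc_mean
    j
  }
  amb <- mk(NULL)
  dro <- mk(list(start_day = 3, end_day = 28, rewet_mm = 40))
  # early-mid exclusion: the store has shrunk but roots still draw fully
  win <- as.Date(intersect(as.Date("2020-06-01") + 5:11,
                           intersect(amb$date, dro$date)),
                 origin = "1970-01-01")
  a <- amb[amb$date %in% win, ]
  d <- dro[dro$date %in% win, ]
  expect_gt(nrow(d), 0)
  expect_lt(mean(d$swc_mean), mean(a$swc_mean))
  expect_gt(mean(d$rwu_swc), mean(a$rwu_swc))
  # and uptake itself declines as the drought deepens
  late <- dro[dro$date >= as.Date("2020-06-01") + 18 &
                dro$date <= as.Date("2020-06-01") + 27, ]
  expect_lt(mean(late$rwu_mm_h), mean(d$rwu_mm_h))
})
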