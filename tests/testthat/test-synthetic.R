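test_that("landscape generation follows the class weights", {
  # degenerate distribution: a single class everywhere
  sp <- landscape_spec(5, 4, 10, 40, 117, list(farmland = 1), seed = 1)
  g <- gen_landscape(sp)
  expect_true(all(unclass(g) == "farmland"))

  # determinism: identical seed, identical grid
  sp2 <- landscape_spec(10, 10, 10, 40, 117,
                        list(farmland = 0.5, grassland = 0.5), seed = 42)
  expect_identical(unclass(gen_landscape(sp2)), unclass(gen_landscape(sp2)))

  # binomial check at 1e4 pixels: farmland fraction within 0.5 +/- 0.02
  sp3 <- landscape_spec(100, 100, 10, 40, 117,
                        list(farmland = 0.5, grassland = 0.5), seed = 7)
  frac <- mean(unclass(gen_landscape(sp3)) == "farmland")
  expect_lt(abs(frac - 0.5), 0.02)

  # invalid weights rejected
  expect_error(landscape_spec(5, 5, 10, 40, 117, list(farmland = 0.7)),
               "sum to 1")
  expect_error(landscape_spec(5, 5, 10, 40, 117, list(city = 1)),
               "unknown")
})

test_that("EVI generator records the analytic green-up truth", {
  sp <- landscape_spec(1, 1, 10, 40, 117, list(grassland = 1), seed = 1)
  g <- gen_landscape(sp)
  p <- evi_params(midpoint = 100, rate = 0.2, noise_sd = 0,
                  lat_gradient = 0, pixel_sd = 0)
  evi <- gen_evi_series(p, g, seed = 1)
  expect_equal(attr(evi, "truth")[1, 1], 100 - log(2 + sqrt(3)) / 0.2,
               tolerance = 1e-10)

  # amplitude zero: flat series, undefined truth
  evi0 <- gen_evi_series(evi_params(amplitude = 0, noise_sd = 0), g,
                         seed = 1)
  expect_true(is.na(attr(evi0, "truth")[1, 1]))
  expect_lt(diff(range(evi0$values)), 1e-12)

  # latitudinal gradient: 2 d/deg and rows 3 deg apart shift truth by 6 d
  sp2 <- landscape_spec(2, 1, 110.574 * 3, 40, 117, list(grassland = 1),
                        seed = 1)
  g2 <- gen_landscape(sp2)
  e2 <- gen_evi_series(evi_params(noise_sd = 0, lat_gradient = 2,
                                  pixel_sd = 0), g2, seed = 1)
  expect_equal(attr(e2, "truth")[2, 1] - attr(e2, "truth")[1, 1], 6,
               tolerance = 1e-9)

  # values clipped to the index range
  evi <- fx_evi()
  expect_true(all(evi$values >= -0.2 & evi$values <= 1))
  expect_identical(evi$days, as.integer(seq(1, 210, by = 8)))
})

test_that("snow generator emits a bounded series with phase-date truth", {
  sp <- landscape_spec(1, 1, 10, 40, 117, list(grassland = 1), seed = 1)
  g <- gen_landscape(sp)
  p <- snow_params(s_high = 100, s_low = 0, t1 = 60, t2 = 100,
                   noise_sd = 0, lat_gradient = 0, pixel_sd = 0)
  snow <- gen_snow_series(p, g, seed = 1)
  tr <- attr(snow, "truth")
  expect_equal(unname(c(tr$d25[1, 1], tr$d50[1, 1], tr$d75[1, 1],
                        tr$d100[1, 1])), c(70, 80, 90, 100))
  expect_true(all(snow$values >= 0 & snow$values <= 100))
  expect_length(snow$days, 210)

  # near-step melt keeps phase dates inside [t1, t2]
  ps <- snow_params(t1 = 79, t2 = 80, noise_sd = 0, lat_gradient = 0,
                    pixel_sd = 0)
  s2 <- gen_snow_series(ps, g, seed = 1)
  tr2 <- attr(s2, "truth")
  for (ph in tr2) expect_true(ph[1, 1] >= 79 && ph[1, 1] <= 80)

  # determinism
  s3 <- gen_snow_series(snow_params(), fx_landscape(), seed = 9)
  s4 <- gen_snow_series(snow_params(), fx_landscape(), seed = 9)
  expect_identical(s3$values, s4$values)
})

test_that("d50 recovery from noisy snow series is unbiased within 1.5 days", {
  sp <- landscape_spec(10, 10, 40, 40, 117, list(grassland = 1), seed = 2)
  g <- gen_landscape(sp)
  snow <- gen_snow_series(snow_params(noise_sd = 5), g, seed = 21)
  ms <- snowmelt_surfaces(snow)
  bias <- mean(ms$maps$d50 - attr(snow, "truth")$d50)
  expect_lt(abs(bias), 1.5)
})

test_that("simulated arrivals equal the cue date plus the lag", {
  # zero lag, zero noise: arrival day is the rounded cue date
  sim <- gen_tracks(bird_scenario(cue = "melt75", true_lag_days = 0,
                                  lag_noise_sd = 0, n_tracks = 10,
                                  seed = 3),
                    fx_truth_stack(), fx_landscape(), fixes = FALSE)
  tr <- sim$truth[sim$truth$role != "winter", ]
  expect_true(all(abs(tr$true_arrival - tr$cue_date) <= 0.5))

  # fixed offset shows up verbatim
  sim2 <- gen_tracks(bird_scenario(cue = "melt75", true_lag_days = 2,
                                   lag_noise_sd = 0, n_tracks = 10,
                                   seed = 3),
                     fx_truth_stack(), fx_landscape(), fixes = FALSE)
  tr2 <- sim2$truth[sim2$truth$role != "winter", ]
  expect_true(all(abs(tr2$true_arrival - tr2$cue_date - 2) <= 0.5))

  # determinism of the full generator
  scen <- bird_scenario(cue = "greenup", n_tracks = 3, seed = 8)
  a <- gen_tracks(scen, fx_truth_stack(), fx_landscape())
  b <- gen_tracks(scen, fx_truth_stack(), fx_landscape())
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$truth, b$truth)
})

test_that("fix cadence matches the residency length", {
  scen <- bird_scenario(cue = "melt75", n_tracks = 4, fix_interval = 2,
                        seed = 12)
  sim <- gen_tracks(scen, fx_truth_stack(), fx_landscape())
  tr <- sim$truth
  fx <- sim$tracks
  for (i in which(tr$role == "stopover")) {
    tid <- tr$track_id[i]
    f <- fx[fx$track_id == tid, ]
    day <- floor(as.numeric(difftime(f$timestamp,
                                     fx_ts(1, 0), units = "days"))) + 1
    n_site <- sum(day >= tr$true_arrival[i] & day <= tr$departure_day[i] &
                    haversine_km(f$lon, f$lat, tr$lon[i], tr$lat[i]) < 50)
    stay <- tr$departure_day[i] - tr$true_arrival[i] + 1
    expect_equal(n_site, 12 * stay, tolerance = 0.04)
  }
})

test_that("tracks and truth round-trip through CSV", {
  scen <- bird_scenario(n_tracks = 2, seed = 5)
  sim <- gen_tracks(scen, fx_truth_stack(), fx_landscape())
  tf <- tempfile(fileext = ".csv")
  write_tracks_csv(sim$tracks, tf)
  back <- read_tracks_csv(tf)
  expect_equal(back$timestamp, sim$tracks$timestamp)
  expect_equal(back$lon, sim$tracks$lon, tolerance = 1e-9)
  unlink(tf)
})

test_that("raster series round-trips through the portable CSV layout", {
  snow <- gen_snow_series(snow_params(),
                          gen_landscape(landscape_spec(3, 2, 40, 40, 117,
                                                       list(grassland = 1),
                                                       seed = 1)),
                          seed = 2)
  tf <- tempfile(fileext = ".csv")
  write_raster_series(snow, tf)
  back <- read_raster_series(tf)
  expect_equal(back$values, snow$values, tolerance = 1e-6)
  expect_identical(back$days, snow$days)
  expect_equal(back$lat, snow$lat, tolerance = 1e-9)
  expect_identical(back$kind, "snow")
  unlink(tf)
})
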