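# Shared study-conditions fixtures, built lazily and cached for the run.
# The "standard world" is a 24 x 20 grid of 40-km pixels with its
# south-west corner at 40 N, 117 E (latitudes ~40-48.7 N), default EVI and
# snow parameters, and truth surfaces recorded by the generators.

.fx <- new.env(parent = emptyenv())

fx_landscape <- function() {
  if (is.null(.fx$grid)) {
    spec <- landscape_spec(24, 20, 40, 40, 117,
                           list(farmland = 0.45, grassland = 0.2,
                                wetland = 0.2, water = 0.05, forest = 0.05,
                                shrubland = 0.04, other = 0.01),
                           seed = 101)
    .fx$grid <- gen_landscape(spec)
  }
  .fx$grid
}

fx_evi <- function() {
  if (is.null(.fx$evi))
    .fx$evi <- gen_evi_series(evi_params(), fx_landscape(), seed = 102)
  .fx$evi
}

fx_snow <- function() {
  if (is.null(.fx$snow))
    .fx$snow <- gen_snow_series(snow_params(), fx_landscape(), seed = 103)
  .fx$snow
}

# truth-surface stack: the generative resource dates
fx_truth_stack <- function() {
  if (is.null(.fx$truth_stack)) {
    evi <- fx_evi(); snow <- fx_snow()
    .fx$truth_stack <- resource_stack(attr(evi, "truth"),
                                      attr(snow, "truth"),
                                      lat = evi$lat, lon = evi$lon)
  }
  .fx$truth_stack
}

# retrieved-surface stack: what the phenology/snowmelt modules recover
fx_retrieved_stack <- function() {
  if (is.null(.fx$retr_stack)) {
    gs <- greenup_surfaces(fx_evi())
    ms <- snowmelt_surfaces(fx_snow())
    .fx$retr_stack <- resource_stack(gs$map, ms$maps,
                                     lat = gs$lat, lon = gs$lon)
  }
  .fx$retr_stack
}

# one simulated cohort: sites straight from the generator truth
fx_sites <- function(cue = "melt75", true_lag = 2, lag_noise = 1,
                     n_tracks = 50, seed = 1L) {
  sim <- gen_tracks(bird_scenario(cue = cue, true_lag_days = true_lag,
                                  lag_noise_sd = lag_noise,
                                  n_tracks = n_tracks, seed = seed),
                    fx_truth_stack(), fx_landscape(), fixes = FALSE)
  sites_from_truth(sim$truth)
}

# timestamps on the UTC+8 civil grid, as the generator emits them
fx_ts <- function(day, hour, year = 2021) {
  as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC") +
    (day - 1) * 86400 + hour * 3600 - 8 * 3600
}
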