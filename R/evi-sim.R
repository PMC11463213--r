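#' Parameters of the synthetic vegetation-index seasonal curve
#'
#' Each pixel's latent EVI trajectory is a double logistic:
#' \deqn{EVI(t) = baseline + amplitude \left[\frac{1}{1+e^{-b(t-m)}} -
#'   \frac{1}{1+e^{-b_s(t-m_s)}}\right]}
#' with a spring rise (midpoint `m`, rate `b`) and an autumn senescence term
#' (midpoint `sen_midpoint`, rate `sen_rate`). The latent green-up day of a
#' pixel is the argmax of the second derivative of the rising logistic,
#' which has the closed form \eqn{m - \ln(2+\sqrt{3})/b}; this is the ground
#' truth that retrieval tests recover.
#'
#' The spring midpoint shifts with latitude (`lat_gradient` days per degree
#' north of the landscape origin) plus an independent per-pixel Gaussian
#' jitter (`pixel_sd`), emulating local phenological heterogeneity.
#'
#' @param baseline,amplitude Index units; `amplitude = 0` yields a flat
#'   series whose green-up is undefined.
#' @param midpoint Julian day of the spring-logistic midpoint, in [1, 210].
#' @param rate Per-day logistic rate `b > 0`.
#' @param sen_midpoint,sen_rate Senescence midpoint / rate.
#' @param noise_sd Observation noise sd, index units.
#' @param lat_gradient Days of phenological delay per degree latitude.
#' @param pixel_sd Per-pixel midpoint jitter sd, days.
#' @return An `evi_params` list.
#' @export
evi_params <- function(baseline = 0.12, amplitude = 0.4, midpoint = 100,
                       rate = 0.2, sen_midpoint = 270, sen_rate = 0.08,
                       noise_sd = 0.02, lat_gradient = 3, pixel_sd = 5) {
  stopifnot(amplitude >= 0, rate > 0, midpoint >= 1, midpoint <= 210,
            noise_sd >= 0, pixel_sd >= 0)
  structure(as.list(environment()), class = "evi_params")
}

# analytic argmax of d2/dt2 of the rising logistic a/(1+exp(-b(t-m)))
greenup_truth_day <- function(m, b) m - log(2 + sqrt(3)) / b

#' Generate a synthetic 8-day EVI raster series with known green-up truth
#'
#' Samples the latent double-logistic curve of every pixel at the 8-day
#' composite days 1, 9, 17, ... (within day 1..210), adds Gaussian noise and
#' clips to \[-0.2, 1\]. The latent green-up day of each pixel is recorded in
#' the `truth` attribute (matrix row x col, `NA` when `amplitude == 0`).
#'
#' @param params an [evi_params()].
#' @param grid a `landcover_grid` (supplies the georeference).
#' @param seed Integer RNG seed.
#' @return A `raster_series` (kind `"evi"`) with attribute `truth`.
#' @export
gen_evi_series <- function(params, grid, seed = 1L) {
  stopifnot(inherits(params, "evi_params"), inherits(grid, "landcover_grid"))
  set.seed(seed)
  lat <- attr(grid, "lat"); lon <- attr(grid, "lon")
  nr <- length(lat); nc <- length(lon)
  days <- seq(1, 210, by = 8)
  lat0 <- lat[1] - 0.5 * (if (nr > 1) diff(lat[1:2]) else 0)
  m_px <- outer(params$midpoint + params$lat_gradient * (lat - lat0),
                rep(1, nc)) +
    matrix(stats::rnorm(nr * nc, 0, params$pixel_sd), nr, nc)
  truth <- if (params$amplitude > 0) {
    greenup_truth_day(m_px, params$rate)
  } else matrix(NA_real_, nr, nc)
  vals <- array(NA_real_, dim = c(length(days), nr, nc))
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    m <- m_px[r, cc]
    latent <- params$baseline + params$amplitude *
      (stats::plogis(params$rate * (days - m)) -
         stats::plogis(params$sen_rate * (days - params$sen_midpoint)))
    vals[, r, cc] <- pmin(1, pmax(-0.2,
      latent + stats::rnorm(length(days), 0, params$noise_sd)))
  }
  out <- raster_series(vals, days, lat, lon, kind = "evi")
  attr(out, "truth") <- truth
  out
}
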