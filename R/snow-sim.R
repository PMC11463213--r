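#' Parameters of the synthetic snow-cover seasonal curve
#'
#' The latent daily snow-cover fraction of a pixel is three-piece linear: a
#' winter plateau at `s_high` percent up to melt onset `t1`, a linear
#' decline to `s_low` at melt end `t2`, and a plateau at `s_low` after.
#' The latent melt-phase dates follow by linear interpolation: the day the
#' curve has lost a fraction f of the melt range is
#' `t1 + f * (t2 - t1)`, so d25/d50/d75/d100 are ground truth for the
#' segmented-regression retrieval. Melt timing shifts with latitude
#' (`lat_gradient` days/degree) and both breakpoints get independent
#' per-pixel jitter (`pixel_sd`), which decorrelates the four phases across
#' pixels.
#'
#' @param s_high Winter plateau, percent in (0, 100].
#' @param s_low Post-melt plateau, percent, `s_low < s_high`.
#' @param t1,t2 Melt onset / end, Julian days with `1 <= t1 < t2 <= 210`.
#' @param noise_sd Observation noise sd, percent.
#' @param lat_gradient Days of delay per degree latitude.
#' @param pixel_sd Per-pixel breakpoint jitter sd, days.
#' @return A `snow_params` list.
#' @export
snow_params <- function(s_high = 95, s_low = 0, t1 = 55, t2 = 85,
                        noise_sd = 5, lat_gradient = 3, pixel_sd = 5) {
  stopifnot(s_high > 0, s_high <= 100, s_low >= 0, s_low < s_high,
            t1 >= 1, t1 < t2, t2 <= 210, noise_sd >= 0, pixel_sd >= 0)
  structure(as.list(environment()), class = "snow_params")
}

#' Generate a synthetic daily snow-cover raster series with melt-date truth
#'
#' Daily series on days 1..210; latent three-piece curve plus Gaussian noise
#' clipped to \[0, 100\]. Latent d25/d50/d75/d100 dates are recorded in the
#' `truth` attribute, a list of four row x col matrices.
#'
#' @param params a [snow_params()].
#' @param grid a `landcover_grid`.
#' @param seed Integer RNG seed.
#' @return A `raster_series` (kind `"snow"`) with attribute `truth`
#'   (list `d25`, `d50`, `d75`, `d100`).
#' @export
gen_snow_series <- function(params, grid, seed = 1L) {
  stopifnot(inherits(params, "snow_params"), inherits(grid, "landcover_grid"))
  set.seed(seed)
  lat <- attr(grid, "lat"); lon <- attr(grid, "lon")
  nr <- length(lat); nc <- length(lon)
  days <- 1:210
  lat0 <- lat[1] - 0.5 * (if (nr > 1) diff(lat[1:2]) else 0)
  shift <- params$lat_gradient * (lat - lat0)
  t1_px <- outer(params$t1 + shift, rep(1, nc)) +
    matrix(stats::rnorm(nr * nc, 0, params$pixel_sd), nr, nc)
  t2_px <- outer(params$t2 + shift, rep(1, nc)) +
    matrix(stats::rnorm(nr * nc, 0, params$pixel_sd), nr, nc)
  # keep melt window ordered and inside the analysis year
  bad <- t2_px < t1_px + 1
  t2_px[bad] <- t1_px[bad] + 1
  t1_px <- pmin(pmax(t1_px, 2), 200)
  t2_px <- pmin(pmax(t2_px, t1_px + 1), 209)
  truth <- lapply(c(d25 = 0.25, d50 = 0.5, d75 = 0.75, d100 = 1),
                  function(f) t1_px + f * (t2_px - t1_px))
  vals <- array(NA_real_, dim = c(length(days), nr, nc))
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    frac <- pmin(1, pmax(0, (days - t1_px[r, cc]) /
                              (t2_px[r, cc] - t1_px[r, cc])))
    latent <- params$s_high - frac * (params$s_high - params$s_low)
    vals[, r, cc] <- pmin(100, pmax(0,
      latent + stats::rnorm(length(days), 0, params$noise_sd)))
  }
  out <- raster_series(vals, days, lat, lon, kind = "snow")
  attr(out, "truth") <- truth
  out
}
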