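#' Three-piece segmented regression of a daily snow-cover series
#'
#' Fits, by least squares, a continuous piecewise-linear model with a level
#' winter plateau, a declining melt segment and a level post-melt plateau:
#' cover(t) = s_high for t <= t1, linear from s_high to s_low on [t1, t2],
#' s_low for t >= t2. Breakpoints are found by exhaustive search over all
#' integer day pairs t1 < t2 within the observed range; conditional on
#' (t1, t2) the plateau levels and slope are solved in closed form, with the
#' declining slope constrained to be <= 0 (clamped to a flat fit when the
#' unconstrained slope would be positive). Missing days are simply omitted
#' from the residual sum of squares.
#'
#' Series whose observed range is below `min_range` percent-points carry no
#' usable melt signal and return a `no_melt` sentinel fit.
#'
#' @param cover Numeric vector of snow-cover percentages (0-100); `NA`
#'   allowed.
#' @param days Integer Julian days matching `cover` (default
#'   `seq_along(cover)`).
#' @param min_range Minimum observed range (percent-points) below which the
#'   series is declared melt-free (default 5).
#' @return An object of class `melt_fit` with elements `t1`, `t2`,
#'   `s_high`, `s_low`, `d25`, `d50`, `d75`, `d100`, `rss`, `n`, `status`
#'   (`"ok"` or `"no_melt"`).
#' @seealso [melt_phase_dates()]
#' @export
fit_three_piece <- function(cover, days = seq_along(cover), min_range = 5) {
  stopifnot(length(cover) == length(days))
  keep <- !is.na(cover) & !is.na(days)
  x <- as.integer(days[keep]); y <- as.numeric(cover[keep])
  if (length(x) < 20) stop("need at least 20 non-missing days")
  o <- order(x); x <- x[o]; y <- y[o]
  if (diff(range(y)) < min_range) {
    return(structure(list(t1 = NA_integer_, t2 = NA_integer_,
                          s_high = mean(y), s_low = mean(y),
                          d25 = NA_real_, d50 = NA_real_, d75 = NA_real_,
                          d100 = NA_real_, rss = sum((y - mean(y))^2),
                          n = length(y), status = "no_melt"),
                     class = "melt_fit"))
  }
  dmin <- x[1]; dmax <- x[length(x)]
  # cumulative sums indexed by day, so every (t1, t2) pair costs O(1)
  span <- dmax - dmin + 1L
  acc <- function(v) {
    a <- numeric(span); a[x - dmin + 1L] <- v; cumsum(a)
  }
  Cn <- acc(rep(1, length(x))); Cy <- acc(y); Cx <- acc(as.numeric(x))
  Cxx <- acc(as.numeric(x)^2); Cxy <- acc(as.numeric(x) * y)
  n_tot <- length(x); Sy_tot <- sum(y); Syy <- sum(y^2) - Sy_tot^2 / n_tot

  t1 <- rep(dmin:(dmax - 1L), times = (dmax - 1L) - (dmin:(dmax - 1L)) + 1L)
  t2 <- unlist(lapply(dmin:(dmax - 1L), function(a) (a + 1L):dmax))
  ia <- t1 - dmin + 1L; ib <- t2 - 1L - dmin + 1L   # window = (t1, t2) strict
  nW <- Cn[ib] - Cn[ia]; SyW <- Cy[ib] - Cy[ia]
  SxW <- Cx[ib] - Cx[ia]; SxxW <- Cxx[ib] - Cxx[ia]
  SxyW <- Cxy[ib] - Cxy[ia]
  nA <- n_tot - Cn[ib]; SyA <- Sy_tot - Cy[ib]
  w <- as.numeric(t2 - t1)
  S1 <- (SxW - t1 * nW) / w + nA
  S2 <- (SxxW - 2 * t1 * SxW + t1^2 * nW) / w^2 + nA
  Sb <- (SxyW - t1 * SyW) / w + SyA
  Sxx <- S2 - S1^2 / n_tot
  Sxy <- Sb - S1 * Sy_tot / n_tot
  cc <- ifelse(Sxx > 1e-12, Sxy / Sxx, 0)
  cc <- pmin(cc, 0)                                  # decline only
  rss <- Syy - 2 * cc * Sxy + cc^2 * Sxx
  best <- which.min(rss)                             # ties: smallest t1, t2
  c_hat <- cc[best]
  a_hat <- (Sy_tot - c_hat * S1[best]) / n_tot
  fit <- structure(list(t1 = t1[best], t2 = t2[best],
                        s_high = a_hat, s_low = a_hat + c_hat,
                        rss = max(0, rss[best]), n = n_tot, status = "ok"),
                   class = "melt_fit")
  fit[c("d25", "d50", "d75", "d100")] <-
    as.list(melt_phase_dates(fit, c(25, 50, 75, 100)))
  fit
}

#' Melt-phase dates from a fitted three-piece model
#'
#' For a fraction f (percent of the melt range lost), the phase date is the
#' earliest day at which the fitted cover drops to
#' `s_high - (f/100) * (s_high - s_low)`; on the linear decline this is
#' `t1 + (f/100) * (t2 - t1)`, and f = 100 returns `t2` (end of melt)
#' exactly. These dates are used as relative seed-availability surrogates:
#' the more snow has melted, the more post-harvest seed is exposed.
#'
#' @param fit a `melt_fit`.
#' @param fractions Percentages in (0, 100] (default `c(25, 50, 75, 100)`).
#' @return Named numeric vector of Julian days (`NA` for `no_melt` fits).
#' @export
melt_phase_dates <- function(fit, fractions = c(25, 50, 75, 100)) {
  stopifnot(inherits(fit, "melt_fit"), all(fractions > 0 & fractions <= 100))
  out <- setNames(rep(NA_real_, length(fractions)),
                  paste0("d", fractions))
  if (identical(fit$status, "no_melt")) return(out)
  out[] <- fit$t1 + fractions / 100 * (fit$t2 - fit$t1)
  out
}

#' @export
print.melt_fit <- function(x, ...) {
  if (identical(x$status, "no_melt")) {
    cat(sprintf("<melt_fit> no melt signal (n = %d, level %.1f%%)\n",
                x$n, x$s_high))
  } else {
    cat(sprintf(
      "<melt_fit> plateaus %.1f%% -> %.1f%%, melt day %d..%d (rss %.2f, n %d)\n",
      x$s_high, x$s_low, x$t1, x$t2, x$rss, x$n))
    cat(sprintf("  phases d25/d50/d75/d100: %.2f / %.2f / %.2f / %.2f\n",
                x$d25, x$d50, x$d75, x$d100))
  }
  invisible(x)
}

#' Per-pixel melt-phase surfaces from a snow raster series
#'
#' Applies [fit_three_piece()] to every pixel and returns the four phase
#' surfaces plus a per-pixel fit table.
#'
#' @param snow a `raster_series` of kind `"snow"`.
#' @param min_range forwarded to [fit_three_piece()].
#' @return list with `maps` (matrices `d25`, `d50`, `d75`, `d100`),
#'   `table` (data.frame pixel_id, row, col, t1, t2, s_high, s_low,
#'   d25..d100, rss, status) and the georeference.
#' @export
snowmelt_surfaces <- function(snow, min_range = 5) {
  stopifnot(inherits(snow, "raster_series"))
  nr <- length(snow$lat); nc <- length(snow$lon)
  maps <- lapply(c("d25", "d50", "d75", "d100"),
                 function(p) matrix(NA_real_, nr, nc))
  names(maps) <- c("d25", "d50", "d75", "d100")
  rows <- vector("list", nr * nc)
  k <- 0
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    k <- k + 1
    f <- fit_three_piece(pixel_series(snow, r, cc), snow$days,
                         min_range = min_range)
    for (p in names(maps)) maps[[p]][r, cc] <- f[[p]]
    rows[[k]] <- data.frame(pixel_id = sprintf("px_%d_%d", r, cc),
                            row = r, col = cc,
                            t1 = f$t1, t2 = f$t2,
                            s_high = f$s_high, s_low = f$s_low,
                            d25 = f$d25, d50 = f$d50, d75 = f$d75,
                            d100 = f$d100, rss = f$rss, status = f$status)
  }
  list(maps = maps, table = do.call(rbind, rows),
       lat = snow$lat, lon = snow$lon)
}
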