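#' Pure-pixel mask for phenology retrieval
#'
#' Vegetation green-up is only retrieved on pixels dominated by herbaceous
#' cover (wetland, grassland, shrubland): the mask is `TRUE` iff the
#' herbaceous proportion within the cell is strictly larger than 0.5.
#'
#' @param labels Character vector of fine land-cover labels inside the cell;
#'   labels are first aggregated to the seven classes via
#'   [aggregate_classes()].
#' @return logical scalar.
#' @export
pure_pixel_mask <- function(labels) {
  agg <- aggregate_classes(labels)
  mean(agg %in% c("wetland", "grassland", "shrubland")) > 0.5
}

#' Smooth an 8-day composite series and upsample to daily resolution
#'
#' Two smoothers are available. `"logistic"` (the retrieval default) fits a
#' rising four-parameter logistic
#' `base + amp / (1 + exp(-b (t - m)))` to the composites by
#' Levenberg-Marquardt least squares and evaluates the fitted curve daily;
#' this is the standard choice for curvature-based phenology retrieval,
#' because the fitted curve is analytic at daily resolution and its
#' curvature maximum is therefore localisable well below the composite
#' cadence. `"sg"` applies Savitzky-Golay smoothing (window 5 composites,
#' order 2) with reflection padding, then cubic-spline interpolation to
#' daily steps; it is model-free and reproduces locally quadratic signals
#' exactly (away from the padded endpoints), but a 5-composite window spans
#' 33 days and biases the curvature peak of a sharp spring rise by several
#' days, so it serves as the fallback when the logistic fit does not
#' converge (and for series that are not spring-rise shaped).
#'
#' @param values Composite EVI values.
#' @param days Composite Julian days, strictly increasing (default 8-day
#'   cadence from day 1).
#' @param method `"logistic"` or `"sg"`.
#' @param window,order Savitzky-Golay window (composites, odd) and
#'   polynomial order, for `method = "sg"`.
#' @return list with `days` (daily integer grid spanning the composites),
#'   `values`, and `method` (the smoother actually used).
#' @export
smooth_and_upsample <- function(values, days = seq(1, by = 8,
                                                   length.out = length(values)),
                                method = c("logistic", "sg"),
                                window = 5, order = 2) {
  method <- match.arg(method)
  stopifnot(length(values) == length(days), all(diff(days) > 0),
            window %% 2 == 1, order < window)
  n <- length(values)
  if (n < window) stop("need at least ", window, " composites")
  daily <- seq(days[1], days[n])
  if (method == "logistic") {
    fitted <- fit_rising_logistic(values, days, daily)
    if (!is.null(fitted))
      return(list(days = daily, values = fitted, method = "logistic"))
  }
  h <- (window - 1) / 2
  padded <- c(values[(h + 1):2], values, values[(n - 1):(n - h)])
  sm <- signal::sgolayfilt(padded, p = order, n = window)
  sm <- sm[(h + 1):(h + n)]
  list(days = daily,
       values = stats::spline(days, sm, xout = daily, method = "fmm")$y,
       method = "sg")
}

# rising-logistic least squares; NULL when the fit fails or is degenerate
fit_rising_logistic <- function(values, days, daily) {
  base <- min(values); amp <- diff(range(values))
  if (amp <= 0) return(NULL)
  m0 <- days[which.min(abs(values - (base + amp / 2)))]
  co <- tryCatch({
    ft <- minpack.lm::nlsLM(
      v ~ base + amp * stats::plogis(b * (t - m)),
      data = list(v = values, t = days),
      start = list(base = base, amp = amp, m = m0, b = 0.1),
      lower = c(-Inf, 1e-9, min(days) - 100, 1e-4),
      upper = c(Inf, Inf, max(days) + 100, 2),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    stats::coef(ft)
  }, error = function(e) NULL)
  if (is.null(co)) return(NULL)
  as.numeric(co[["base"]] + co[["amp"]] *
               stats::plogis(co[["b"]] * (daily - co[["m"]])))
}

#' Green-up date by the second-derivative method
#'
#' The spring vegetation-emergence day is the day at which the discrete
#' central-difference second derivative of the smoothed daily EVI series is
#' maximal, restricted to the rising limb (between the series start and the
#' day of the annual EVI maximum). The discrete argmax is refined to
#' sub-day resolution by fitting a parabola through the second-derivative
#' values at the argmax and its two neighbours `h` days away (default 1;
#' use the composite cadence, 8, for series upsampled by spline, whose
#' curvature is only piecewise linear between composite knots). This
#' targets the onset of the logistic rise: for a
#' logistic with midpoint m and rate b, the continuous argmax is
#' m - ln(2 + sqrt(3))/b.
#'
#' Series whose total range is below `min_range` index units are flagged
#' `flat` and get no date; all-missing input is flagged `masked`.
#'
#' @param daily list as returned by [smooth_and_upsample()] (elements
#'   `days`, `values`).
#' @param min_range Flat-series guard in index units (default 0.05).
#' @param h Vertex-refinement half-width in days (default 1).
#' @return list with `greenup_day` (Julian day, possibly fractional, or
#'   `NA`) and `qa_flag` (`"ok"`, `"flat"` or `"masked"`).
#' @export
greenup_date <- function(daily, min_range = 0.05, h = 1) {
  v <- daily$values; d <- daily$days
  if (all(is.na(v))) return(list(greenup_day = NA_real_, qa_flag = "masked"))
  if (diff(range(v, na.rm = TRUE)) < min_range)
    return(list(greenup_day = NA_real_, qa_flag = "flat"))
  n <- length(v)
  pos <- 2:(n - 1)
  d2 <- v[pos + 1] - 2 * v[pos] + v[pos - 1]
  i_max <- which.max(v)
  keep <- pos <= i_max
  if (!any(keep)) keep <- rep(TRUE, length(pos))  # max at the very start
  cand <- which(keep)
  j <- cand[which.max(d2[cand])]
  day <- d[pos[j]]
  # parabolic vertex through the curvature at (day - h, day, day + h)
  if (j - h >= 1 && j + h <= length(pos)) {
    a <- d2[j - h]; b <- d2[j]; cc <- d2[j + h]
    denom <- a - 2 * b + cc
    if (denom < 0) {
      off <- h * 0.5 * (a - cc) / denom
      day <- day + max(-h, min(h, off))
    }
  }
  list(greenup_day = day, qa_flag = "ok")
}

#' Per-pixel green-up surface from an EVI raster series
#'
#' Runs [smooth_and_upsample()] and [greenup_date()] on every pixel,
#' optionally restricted to a pure-pixel mask.
#'
#' @param evi a `raster_series` of kind `"evi"`.
#' @param mask optional logical matrix (row x col); `FALSE` pixels are
#'   flagged `masked`.
#' @param min_range forwarded to [greenup_date()].
#' @return list with `map` (matrix of green-up days), `qa` (matrix of
#'   flags), `table` (per-pixel data.frame) and the georeference.
#' @export
greenup_surfaces <- function(evi, mask = NULL, min_range = 0.05) {
  stopifnot(inherits(evi, "raster_series"))
  nr <- length(evi$lat); nc <- length(evi$lon)
  map <- matrix(NA_real_, nr, nc)
  qa <- matrix("masked", nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!is.null(mask) && !isTRUE(mask[r, cc])) next
    sm <- smooth_and_upsample(pixel_series(evi, r, cc), evi$days)
    g <- greenup_date(sm, min_range = min_range,
                      h = if (identical(sm$method, "sg")) 8 else 1)
    map[r, cc] <- g$greenup_day
    qa[r, cc] <- g$qa_flag
  }
  tab <- data.frame(pixel_id = sprintf("px_%d_%d",
                                       rep(seq_len(nr), nc),
                                       rep(seq_len(nc), each = nr)),
                    row = rep(seq_len(nr), nc),
                    col = rep(seq_len(nc), each = nr),
                    greenup_day = as.vector(map), qa_flag = as.vector(qa))
  list(map = map, qa = qa, table = tab, lat = evi$lat, lon = evi$lon)
}

#' Bundle the five resource-date surfaces
#'
#' The lag-scanned selection model compares five candidate cues: green-up
#' and the four melt phases. This container holds one date matrix per cue on
#' a common grid.
#'
#' @param greenup matrix of green-up days (row x col).
#' @param melt list of matrices `d25`, `d50`, `d75`, `d100`.
#' @param lat,lon georeference vectors.
#' @return object of class `resource_stack`; element `maps` is a named list
#'   `greenup`, `melt25`, `melt50`, `melt75`, `melt100`.
#' @export
resource_stack <- function(greenup, melt, lat, lon) {
  stopifnot(all(c("d25", "d50", "d75", "d100") %in% names(melt)))
  maps <- list(greenup = greenup, melt25 = melt$d25, melt50 = melt$d50,
               melt75 = melt$d75, melt100 = melt$d100)
  for (m in maps) stopifnot(identical(dim(m), dim(greenup)))
  structure(list(maps = maps, lat = lat, lon = lon),
            class = "resource_stack")
}

#' @export
print.resource_stack <- function(x, ...) {
  cat(sprintf("<resource_stack> %d x %d pixels, cues: %s\n",
              nrow(x$maps$greenup), ncol(x$maps$greenup),
              paste(names(x$maps), collapse = ", ")))
  invisible(x)
}

# resource date of a cue at given lon/lat (vectorised)
resource_date_at <- function(stack, cue, lon, lat) {
  stopifnot(cue %in% names(stack$maps))
  px <- locate_pixel(lon, lat, stack$lat, stack$lon, pixel_km = 1)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(px$row) & !is.na(px$col)
  out[ok] <- stack$maps[[cue]][cbind(px$row[ok], px$col[ok])]
  out
}
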