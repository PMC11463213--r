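CUES <- c("greenup", "melt25", "melt50", "melt75", "melt100")

#' Build a presence/absence arrival design
#'
#' For each site, the presence row(s) carry the site's arrival day as
#' `candidate_day`; `n_absence_per_site` absence days are drawn uniformly
#' without replacement from Julian days 1..211 excluding the arrival day.
#' Every row carries a mismatch column per cue,
#' `m_<cue> = candidate_day - resource_date(pixel, cue)`, so a positive
#' mismatch means the candidate day falls after the resource became
#' available at that pixel. Sites whose pixel resolves no resource date for
#' any cue are dropped (with a message).
#'
#' @param sites sites data.frame (needs `track_id`, `site_id`, `lon`,
#'   `lat`, `arrival_day`).
#' @param resources a `resource_stack`.
#' @param n_absence_per_site Absence days per site (default 10).
#' @param seed Integer RNG seed (draws are reproducible).
#' @param presence_unit `"site"` (one presence row per site, at the site
#'   centroid pixel) or `"fix"` (one row per arrival-day fix; requires
#'   `fixes`).
#' @param fixes fix data.frame (with `track_id`, `timestamp`, `lon`,
#'   `lat`), used when `presence_unit = "fix"`.
#' @param year_days Length of the candidate-day window (default 211,
#'   1 Jan-31 Jul).
#' @return data.frame of design rows: `track_id`, `site_id`,
#'   `candidate_day`, `response` (1/0), `m_greenup`, `m_melt25`, ...,
#'   `m_melt100`.
#' @export
build_design <- function(sites, resources, n_absence_per_site = 10,
                         seed = 1L, presence_unit = c("site", "fix"),
                         fixes = NULL, year_days = 211) {
  presence_unit <- match.arg(presence_unit)
  stopifnot(inherits(resources, "resource_stack"))
  set.seed(seed)
  rows <- vector("list", nrow(sites))
  dropped <- 0L
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    rdates <- vapply(CUES, function(cue)
      resource_date_at(resources, cue, s$lon, s$lat), numeric(1))
    if (all(is.na(rdates))) { dropped <- dropped + 1L; next }
    if (presence_unit == "fix" && !is.null(fixes)) {
      fx <- fixes[fixes$track_id == s$track_id, , drop = FALSE]
      yr <- if ("year" %in% names(fx) && nrow(fx)) fx$year[1] else 2021
      fx <- fx[civil_julian_day(fx$timestamp, yr) == s$arrival_day, ,
               drop = FALSE]
      pres_lon <- fx$lon; pres_lat <- fx$lat
      if (!length(pres_lon)) { pres_lon <- s$lon; pres_lat <- s$lat }
    } else {
      pres_lon <- s$lon; pres_lat <- s$lat
    }
    pres <- data.frame(track_id = s$track_id, site_id = s$site_id,
                       candidate_day = s$arrival_day, response = 1L,
                       lon = pres_lon, lat = pres_lat)
    d <- pres
    if (n_absence_per_site > 0) {
      abs_days <- sample(setdiff(seq_len(year_days), s$arrival_day),
                         n_absence_per_site)
      d <- rbind(pres,
                 data.frame(track_id = s$track_id, site_id = s$site_id,
                            candidate_day = abs_days, response = 0L,
                            lon = s$lon, lat = s$lat))
    }
    for (cue in CUES)
      d[[paste0("m_", cue)]] <- d$candidate_day -
        resource_date_at(resources, cue, d$lon, d$lat)
    rows[[i]] <- d[, c("track_id", "site_id", "candidate_day", "response",
                       paste0("m_", CUES))]
  }
  if (dropped) message(dropped, " site(s) dropped: no resolvable resource date")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the arrival resource-selection model at one lag
#'
#' Random-intercept logistic regression of presence/absence on the lagged
#' mismatch: with D = mismatch(cue) - lag,
#' P(presence) = logit^-1(b0 + b2 D^2 + u_track),
#' u_track ~ N(0, sigma^2) integrated by the Laplace approximation
#' (`lme4::glmer`). The concave quadratic (b2 < 0 at any informative fit)
#' peaks the selection probability at D = 0, i.e. where candidate days sit
#' exactly `lag` days after the resource date. Pinning the peak at D = 0 is
#' what makes the lag scan identifiable: adding a free linear term would
#' let the model re-centre itself at any lag and the likelihood profile
#' over lags would be flat. When the estimated random-intercept variance is
#' below 1e-8, or the mixed fit fails, the fixed-effects logistic fit
#' (`stats::glm`) is returned instead (`model = "fixed"`). AIC counts the
#' random-intercept variance as a parameter.
#'
#' @param design design data.frame from [build_design()].
#' @param cue cue name.
#' @param lag lag in days (mismatch scale: positive = arrival after the
#'   resource).
#' @return list: `loglik`, `aic`, `coefficients` (b0, b2), `sigma2`,
#'   `model` (`"mixed"`/`"fixed"`), `converged`, `n`.
#' @export
fit_rsf <- function(design, cue, lag) {
  stopifnot(cue %in% CUES)
  delta <- design[[paste0("m_", cue)]] - lag
  d <- data.frame(response = design$response, delta = delta,
                  track_id = design$track_id)
  d <- d[!is.na(d$delta), , drop = FALSE]
  if (length(unique(d$response)) < 2)
    stop("design must contain both presences and absences")
  res <- list(model = "fixed", sigma2 = 0, converged = TRUE,
              n = nrow(d))
  d$delta2 <- d$delta^2
  mixed <- if (length(unique(d$track_id)) > 1) {
    tryCatch(suppressWarnings(suppressMessages(
      lme4::glmer(response ~ delta2 + (1 | track_id),
                  data = d, family = stats::binomial(),
                  control = lme4::glmerControl(
                    calc.derivs = FALSE,
                    check.conv.singular = "ignore")))),
      error = function(e) NULL)
  } else NULL
  sigma2 <- if (!is.null(mixed))
    as.numeric(lme4::VarCorr(mixed)$track_id[1]) else 0
  if (!is.null(mixed) && sigma2 >= 1e-8) {
    ll <- as.numeric(stats::logLik(mixed))
    res$model <- "mixed"
    res$sigma2 <- sigma2
    res$loglik <- ll
    res$aic <- 2 * 3 - 2 * ll
    res$coefficients <- lme4::fixef(mixed)
    res$converged <- length(mixed@optinfo$conv$lme4) == 0
  } else {
    fixed <- suppressWarnings(
      stats::glm(response ~ delta2, data = d,
                 family = stats::binomial()))
    ll <- as.numeric(stats::logLik(fixed))
    res$loglik <- ll
    res$aic <- 2 * 2 - 2 * ll
    res$coefficients <- stats::coef(fixed)
    res$converged <- fixed$converged
  }
  names(res$coefficients) <- c("b0", "b2")
  res
}

#' Scan temporal lags and select the AIC-optimal lag
#'
#' Fits [fit_rsf()] over an integer lag grid spanning the 10th to 90th
#' percentile of the presence rows' mismatch for the cue (padded by
#' `lag_pad` days on each side so the likelihood-drop crossings are
#' bracketed), selects the lag minimising AIC, interpolates the two
#' crossings where the log-likelihood profile falls 1 unit below its
#' maximum (the dAIC = 2 range), and reports the range width
#' (`difference`). Predictive skill at the optimal lag is scored by
#' [kfold_rs()].
#'
#' `optimal_lag` is on the mismatch scale (positive = arrival after the
#' resource). `lag_paper` is its negation — the convention in which a
#' negative lag means arrival after the resource — and `abs_lag` the
#' magnitude, which is what cue selection uses.
#'
#' @param design design data.frame from [build_design()].
#' @param cue cue name.
#' @param lag_pad Days of padding beyond the percentile span (default 5).
#' @param k,n_bins,seed,reps forwarded to [kfold_rs()]; `k = 0` skips
#'   validation.
#' @return object of class `lag_scan`: `cue`, `lag_grid`, `loglik`, `aic`,
#'   `optimal_lag`, `lag_paper`, `abs_lag`, `range_lo`, `range_hi`,
#'   `difference`, `loglik_max`, `uninformative`, `rs_folds`, `rs_mean`,
#'   `fit` (the top model).
#' @export
scan_lags <- function(design, cue, lag_pad = 5, k = 5, n_bins = 10,
                      seed = 1L, reps = 10) {
  m_pres <- design[design$response == 1, paste0("m_", cue)]
  m_pres <- m_pres[!is.na(m_pres)]
  if (!length(m_pres)) stop("no presence rows with a defined mismatch")
  q <- stats::quantile(m_pres, c(0.1, 0.9), names = FALSE)
  grid <- seq(floor(q[1]) - lag_pad, ceiling(q[2]) + lag_pad)
  fits <- lapply(grid, function(l) fit_rsf(design, cue, l))
  ok <- vapply(fits, function(f) is.finite(f$loglik), logical(1))
  if (!all(vapply(fits[ok], `[[`, logical(1), "converged")))
    warning("some lag fits hit the optimiser's iteration limit ",
            "(expected under quasi-separation); their likelihoods are kept")
  grid <- grid[ok]; fits <- fits[ok]
  if (!length(grid)) stop("no lag produced a finite likelihood")
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  i_opt <- which.min(aic)
  opt <- grid[i_opt]
  ll_max <- ll[i_opt]
  cross <- profile_crossings(grid, ll, ll_max - 1, i_opt)
  uninformative <- diff(range(ll)) < 0.5
  rs <- if (k > 0) kfold_rs(design, cue, opt, k = k, n_bins = n_bins,
                            seed = seed, reps = reps)
        else list(rs_folds = numeric(0), rs_mean = NA_real_)
  structure(list(cue = cue, lag_grid = grid, loglik = ll, aic = aic,
                 optimal_lag = opt, lag_paper = -opt, abs_lag = abs(opt),
                 range_lo = cross[1], range_hi = cross[2],
                 difference = cross[2] - cross[1], loglik_max = ll_max,
                 uninformative = uninformative,
                 rs_folds = rs$rs_folds, rs_mean = rs$rs_mean,
                 fit = fits[[i_opt]]),
            class = "lag_scan")
}

# linear interpolation of the two points where the profile crosses `level`,
# one on each side of the optimum; falls back to the grid edge when the
# profile never drops below the level on that side
profile_crossings <- function(grid, ll, level, i_opt) {
  lo <- grid[1]; hi <- grid[length(grid)]
  if (i_opt > 1) {
    left <- rev(seq_len(i_opt - 1))
    j <- left[which(ll[left] < level)[1]]
    if (!is.na(j))
      lo <- grid[j] + (level - ll[j]) / (ll[j + 1] - ll[j]) *
        (grid[j + 1] - grid[j])
  }
  if (i_opt < length(grid)) {
    right <- seq(i_opt + 1, length(grid))
    j <- right[which(ll[right] < level)[1]]
    if (!is.na(j))
      hi <- grid[j - 1] + (ll[j - 1] - level) / (ll[j - 1] - ll[j]) *
        (grid[j] - grid[j - 1])
  }
  c(lo, hi)
}

#' @export
print.lag_scan <- function(x, ...) {
  cat(sprintf("<lag_scan> cue %s: optimal lag %+d days (arrival %s resource)\n",
              x$cue, x$optimal_lag,
              if (x$optimal_lag >= 0) "after" else "before"))
  cat(sprintf("  dAIC=2 range [%.1f, %.1f], difference %.1f; logLik %.2f%s\n",
              x$range_lo, x$range_hi, x$difference, x$loglik_max,
              if (x$uninformative) " [uninformative]" else ""))
  if (length(x$rs_folds))
    cat(sprintf("  k-fold rs: mean %.3f over %d fold scores\n",
                x$rs_mean, length(x$rs_folds)))
  invisible(x)
}

#' @export
summary.lag_scan <- function(object, ...) {
  df <- data.frame(cue = object$cue, optimal_lag = object$optimal_lag,
                   lag_paper = object$lag_paper, abs_lag = object$abs_lag,
                   range_lo = object$range_lo, range_hi = object$range_hi,
                   difference = object$difference,
                   loglik = object$loglik_max, rs_mean = object$rs_mean,
                   model = object$fit$model,
                   uninformative = object$uninformative)
  class(df) <- c("summary.lag_scan", "data.frame")
  df
}

#' @export
coef.lag_scan <- function(object, ...) object$fit$coefficients

#' @export
plot.lag_scan <- function(x, ...) {
  graphics::plot(x$lag_grid, x$loglik, type = "b", pch = 16,
                 xlab = "lag (days, arrival minus resource)",
                 ylab = "log-likelihood",
                 main = sprintf("Lag profile, cue %s", x$cue), ...)
  graphics::abline(h = x$loglik_max - 1, lty = 2)
  graphics::abline(v = c(x$range_lo, x$range_hi), lty = 3)
  graphics::points(x$optimal_lag, x$loglik_max, col = 2, pch = 16)
  invisible(x)
}

#' k-fold Spearman validation of the selection model
#'
#' Folds split by track (never by row, preserving random-effect integrity).
#' Per fold: the model is refitted on the other folds at the given lag,
#' held-out rows are scored on the fixed effects (new tracks have no
#' estimated random intercept, so the refit inside validation is the
#' fixed-effects logistic fit), scores are cut into `n_bins` equal-width
#' bins, the presence frequency per bin is area-adjusted (validation
#' presences in the bin divided by all available rows in the bin; empty
#' bins are merged with their lower neighbour), and rs is the Spearman rank
#' correlation between bin rank and adjusted frequency.
#'
#' A single fold split yields a noisy score: the binned frequencies are
#' discrete and the split itself is random. `reps` independent fold splits
#' are therefore averaged (repeated k-fold), which leaves the expected
#' score unchanged while shrinking its variance.
#'
#' @param design design data.frame.
#' @param cue cue name.
#' @param lag lag in days.
#' @param k folds (default 5).
#' @param n_bins score bins (default 10).
#' @param seed fold-assignment seed.
#' @param reps independent fold splits averaged (default 10).
#' @return list `rs_folds` (per-fold rs, all splits) and `rs_mean`.
#' @export
kfold_rs <- function(design, cue, lag, k = 5, n_bins = 10, seed = 1L,
                     reps = 10) {
  tracks <- unique(design$track_id)
  if (length(tracks) < k)
    stop("need at least k = ", k, " tracks for k-fold validation")
  delta_all <- design[[paste0("m_", cue)]] - lag
  rs_all <- numeric(0)
  for (r in seq_len(reps)) {
    set.seed(seed + r - 1L)
    fold_of <- setNames(sample(rep(seq_len(k),
                                   length.out = length(tracks))), tracks)
    rs <- numeric(k)
    for (f in seq_len(k)) {
      held <- design$track_id %in% names(fold_of)[fold_of == f]
      train <- !held & !is.na(delta_all)
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, delta_all[train]^2), design$response[train],
                       family = stats::binomial()))
      b <- fit$coefficients
      keep <- held & !is.na(delta_all)
      score <- stats::plogis(b[1] + b[2] * delta_all[keep]^2)
      resp <- design$response[keep]
      breaks <- seq(min(score), max(score), length.out = n_bins + 1)
      breaks[1] <- breaks[1] - 1e-9
      bin <- cut(score, breaks, labels = FALSE)
      n_in <- tabulate(bin, n_bins)
      p_in <- tabulate(bin[resp == 1], n_bins)
      nonempty <- which(n_in > 0)   # empty bins merge into lower neighbour
      freq <- p_in[nonempty] / n_in[nonempty]
      rs[f] <- if (length(freq) > 1 && stats::sd(freq) > 0)
        stats::cor(seq_along(freq), freq, method = "spearman")
      else 0
    }
    rs_all <- c(rs_all, rs)
  }
  list(rs_folds = rs_all, rs_mean = mean(rs_all))
}

#' Scan all five cues
#'
#' @param design design data.frame.
#' @param ... forwarded to [scan_lags()].
#' @return named list of `lag_scan` objects (one per cue).
#' @export
scan_all_cues <- function(design, ...) {
  res <- lapply(CUES, function(cue) scan_lags(design, cue, ...))
  names(res) <- CUES
  res
}

#' Choose the main and specific cue for a species/region
#'
#' Compares the k-fold rs of the plant (green-wave) model with the mean rs
#' of the four snowmelt models; the higher score wins. When snowmelt wins,
#' the specific cue is the snow phase whose optimal lag has the minimal
#' absolute value (ties broken towards the earlier phase). Uninformative
#' snow profiles are excluded from the snow mean.
#'
#' @param results named list of `lag_scan` objects covering all five cues
#'   (as from [scan_all_cues()]).
#' @param region,species bookkeeping labels.
#' @return object of class `cue_assignment`: `winner` (`"plant"` /
#'   `"snowmelt"`), `specific_cue`, `rs_plant`, `rs_snow_mean`,
#'   `abs_lags`, `region`, `species`.
#' @export
choose_cue <- function(results, region = "NCP_core", species = "unknown") {
  stopifnot(all(CUES %in% names(results)))
  snow_cues <- setdiff(CUES, "greenup")
  rs_plant <- results$greenup$rs_mean
  informative <- snow_cues[!vapply(results[snow_cues], `[[`, logical(1),
                                   "uninformative")]
  if (!length(informative)) informative <- snow_cues
  rs_snow <- mean(vapply(results[informative], `[[`, numeric(1), "rs_mean"))
  abs_lags <- vapply(results[snow_cues], `[[`, numeric(1), "abs_lag")
  if (rs_plant > rs_snow) {
    winner <- "plant"; specific <- "greenup"
  } else {
    winner <- "snowmelt"
    cand <- abs_lags[informative]
    specific <- names(cand)[which.min(cand)]   # ties -> earlier phase
  }
  structure(list(winner = winner, specific_cue = specific,
                 rs_plant = rs_plant, rs_snow_mean = rs_snow,
                 abs_lags = abs_lags, region = region, species = species),
            class = "cue_assignment")
}

#' @export
print.cue_assignment <- function(x, ...) {
  cat(sprintf("<cue_assignment> %s @ %s: %s (specific cue %s)\n",
              x$species, x$region, x$winner, x$specific_cue))
  cat(sprintf("  rs plant %.3f vs snow mean %.3f; |lag| per snow cue: %s\n",
              x$rs_plant, x$rs_snow_mean,
              paste(sprintf("%s=%g", names(x$abs_lags), x$abs_lags),
                    collapse = ", ")))
  invisible(x)
}

#' Tabulate lag-scan results in the headline-table layout
#'
#' One row per cue: cue, estimated lag (paper sign convention: negative =
#' arrival after the resource) with the interpolated range, the range width
#' ("difference") and the maximised log-likelihood plus the k-fold rs.
#'
#' @param results named list of `lag_scan` objects.
#' @param region,species labels prepended to every row.
#' @return data.frame.
#' @export
lagscan_table <- function(results, region = "", species = "") {
  do.call(rbind, lapply(results, function(r) data.frame(
    region = region, species = species, cue = r$cue,
    lag = r$lag_paper, range_lo = -r$range_hi, range_hi = -r$range_lo,
    difference = r$difference, loglik = r$loglik_max,
    rs = r$rs_mean, row.names = NULL)))
}
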