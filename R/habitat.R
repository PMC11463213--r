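#' Aggregate fine land-cover labels to the seven analysis classes
#'
#' Deterministic mapping of common fine product labels onto grassland,
#' farmland, water, wetland, forest, shrubland and "other" (barren land,
#' snow and ice, built-up areas). Labels already in the seven-class
#' vocabulary pass through unchanged.
#'
#' @param raw_label character vector of land-cover labels.
#' @return character vector of the seven classes.
#' @export
aggregate_classes <- function(raw_label) {
  map <- c(
    grassland = "grassland", grass = "grassland", meadow = "grassland",
    farmland = "farmland", cropland = "farmland", crop = "farmland",
    paddy = "farmland", rice_paddy = "farmland",
    water = "water", lake = "water", river = "water", waterbody = "water",
    wetland = "wetland", marsh = "wetland", bog = "wetland",
    forest = "forest", woodland = "forest", tree_cover = "forest",
    shrubland = "shrubland", shrub = "shrubland", scrub = "shrubland",
    other = "other", barren = "other", bare = "other", barren_land = "other",
    snow_ice = "other", snow = "other", ice = "other",
    built_up = "other", builtup = "other", urban = "other")
  key <- gsub("[ -]", "_", tolower(raw_label))
  out <- map[key]
  if (anyNA(out))
    stop("unknown land-cover label(s): ",
         paste(unique(raw_label[is.na(out)]), collapse = ", "))
  unname(out)
}

# aggregated class at each fix location
landcover_at <- function(grid, lon, lat) {
  px <- locate_pixel(lon, lat, attr(grid, "lat"), attr(grid, "lon"),
                     attr(grid, "pixel_km"))
  out <- rep(NA_character_, length(lon))
  ok <- !is.na(px$row) & !is.na(px$col)
  out[ok] <- unclass(grid)[cbind(px$row[ok], px$col[ok])]
  out
}

#' Weekly daytime habitat use
#'
#' Weeks are indexed from 1 January (UTC+8 civil dates, week 1 = days
#' 1-7). For each week the proportion of daytime fixes per aggregated
#' land-cover class is reported; a week with no daytime fixes gets
#' `n_fixes = 0` and undefined proportions.
#'
#' @param fixes day/night-labelled fixes (see [label_day_night()]) with
#'   `timestamp`, `lon`, `lat` and optionally `year`.
#' @param landcover a `landcover_grid`.
#' @return data.frame `week`, one proportion column per class, `n_fixes`.
#' @export
weekly_daytime_use <- function(fixes, landcover) {
  stopifnot("daynight" %in% names(fixes))
  yr <- if ("year" %in% names(fixes)) fixes$year[1]
        else as.integer(format(fixes$timestamp[1], "%Y", tz = "UTC"))
  day <- civil_julian_day(fixes$timestamp, yr)
  week <- (day - 1) %/% 7 + 1
  cls <- landcover_at(landcover, fixes$lon, fixes$lat)
  keep <- fixes$daynight == "day" & !is.na(cls)
  weeks <- sort(unique(week))
  out <- lapply(weeks, function(w) {
    ci <- cls[keep & week == w]
    n <- length(ci)
    props <- if (n > 0)
      as.numeric(prop.table(table(factor(ci, LANDCOVER_CLASSES))))
    else rep(NA_real_, length(LANDCOVER_CLASSES))
    df <- as.data.frame(as.list(setNames(props, LANDCOVER_CLASSES)))
    cbind(data.frame(week = w), df, data.frame(n_fixes = n))
  })
  do.call(rbind, out)
}

#' Habitat-switch week
#'
#' The week *before* the first week in which natural habitats (grassland +
#' shrubland + wetland) are used more intensely than farmland. Returns `NA`
#' if farmland stays dominant; returns 0 (switch before observation) when
#' natural use already dominates in the first observed week.
#'
#' @param weekly data.frame from [weekly_daytime_use()].
#' @return integer week index (or `NA`).
#' @export
habitat_switch_week <- function(weekly) {
  stopifnot(nrow(weekly) >= 2)
  natural <- weekly$grassland + weekly$shrubland + weekly$wetland
  cross <- which(!is.na(natural) & natural > weekly$farmland)
  if (!length(cross)) return(NA_integer_)
  w <- weekly$week[cross[1]] - 1L
  if (cross[1] == 1) attr(w, "note") <- "switch before observation window"
  w
}

#' Welch's two-sample t-test from summary statistics
#'
#' t = (mean1 - mean2) / sqrt(var1/n1 + var2/n2), with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value; also
#' returns the 95% CI of the mean difference. When both variances are zero
#' and the means equal, t = 0 with pooled df n1 + n2 - 2.
#'
#' @param n1,mean1,var1 Size, mean and variance of sample 1.
#' @param n2,mean2,var2 Same for sample 2.
#' @return list: `t`, `df`, `p`, `ci95` (length-2), `diff`.
#' @export
welch_t <- function(n1, mean1, var1, n2, mean2, var2) {
  stopifnot(n1 >= 2, n2 >= 2, var1 >= 0, var2 >= 0)
  se2 <- var1 / n1 + var2 / n2
  diff <- mean1 - mean2
  if (se2 == 0) {
    # degenerate zero-variance samples: equal means give t = 0, unequal
    # means an infinite statistic
    df <- n1 + n2 - 2
    t <- if (diff == 0) 0 else sign(diff) * Inf
  } else {
    t <- diff / sqrt(se2)
    df <- se2^2 / ((var1 / n1)^2 / (n1 - 1) + (var2 / n2)^2 / (n2 - 1))
  }
  p <- 2 * stats::pt(-abs(t), df)
  half <- stats::qt(0.975, df) * sqrt(se2)
  list(t = t, df = df, p = p, ci95 = c(diff - half, diff + half),
       diff = diff)
}

#' Farmland vs natural use before and after local vegetation emergence
#'
#' For each track, daytime fixes at its stopover sites are split at the
#' site-local green-up day into a before window (arrival to the day before
#' emergence) and an after window (emergence to departure); the per-track
#' farmland and natural daytime fractions are computed per window and the
#' farmland fractions compared across tracks with [welch_t()]. Tracks with
#' an empty window are skipped.
#'
#' @param fixes day/night-labelled fixes with `track_id`.
#' @param sites sites data.frame (stopover rows are used).
#' @param resources a `resource_stack` (supplies the local green-up day).
#' @param landcover a `landcover_grid`.
#' @return list: `per_track` (data.frame track_id, farmland_before,
#'   farmland_after, natural_before, natural_after), `welch`
#'   ([welch_t()] on farmland before vs after), `n_skipped`.
#' @export
foraging_split <- function(fixes, sites, resources, landcover) {
  stopifnot("daynight" %in% names(fixes))
  st <- sites[sites$role == "stopover", , drop = FALSE]
  natural_cls <- c("grassland", "shrubland", "wetland")
  rows <- list(); skipped <- 0L
  for (tid in unique(st$track_id)) {
    s <- st[st$track_id == tid, , drop = FALSE]
    fx <- fixes[fixes$track_id == tid & fixes$daynight == "day", ,
                drop = FALSE]
    if (!nrow(fx)) { skipped <- skipped + 1L; next }
    yr <- if ("year" %in% names(fx)) fx$year[1] else 2021
    day <- civil_julian_day(fx$timestamp, yr)
    cls <- landcover_at(landcover, fx$lon, fx$lat)
    before <- after <- rep(FALSE, nrow(fx))
    for (i in seq_len(nrow(s))) {
      g <- resource_date_at(resources, "greenup", s$lon[i], s$lat[i])
      if (is.na(g)) next
      in_site <- day >= s$arrival_day[i] & day <= s$departure_day[i]
      before <- before | (in_site & day < g)
      after <- after | (in_site & day >= g)
    }
    if (!any(before) || !any(after)) { skipped <- skipped + 1L; next }
    frac <- function(sel, what) {
      ci <- cls[sel]; ci <- ci[!is.na(ci)]
      if (!length(ci)) return(NA_real_)
      mean(ci %in% what)
    }
    rows[[tid]] <- data.frame(
      track_id = tid,
      farmland_before = frac(before, "farmland"),
      farmland_after = frac(after, "farmland"),
      natural_before = frac(before, natural_cls),
      natural_after = frac(after, natural_cls))
  }
  per_track <- do.call(rbind, rows)
  if (!is.null(per_track)) rownames(per_track) <- NULL
  welch <- if (!is.null(per_track) && nrow(per_track) >= 2) {
    fb <- per_track$farmland_before; fa <- per_track$farmland_after
    welch_t(length(fb), mean(fb), stats::var(fb),
            length(fa), mean(fa), stats::var(fa))
  } else NULL
  list(per_track = per_track, welch = welch, n_skipped = skipped)
}
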