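#' Scenario for simulated migrating birds
#'
#' Each simulated track visits a wintering site, one core stopover on the
#' resource grid and one breeding site further north. The arrival day at the
#' stopover and breeding site equals the site pixel's date for the chosen
#' `cue` plus `true_lag_days` plus Gaussian noise, rounded half-up to an
#' integer Julian day. A positive `true_lag_days` therefore means arrival
#' *after* the resource becomes available (the mismatch scale used
#' throughout the package; see [scan_lags()] for the reporting conventions).
#'
#' @param species_label Free-text species tag.
#' @param cue One of `"greenup"`, `"melt25"`, `"melt50"`, `"melt75"`,
#'   `"melt100"`.
#' @param true_lag_days Signed days added to the cue date.
#' @param lag_noise_sd Sd of the arrival-day noise, days.
#' @param n_tracks Number of bird-year tracks.
#' @param fix_interval GPS fix interval, hours (default 2).
#' @param stopover_stay_days Minimum days at the stopover (default 10); the
#'   actual stay extends until two travel days before breeding arrival,
#'   mirroring birds prolonging their stopover until conditions up north
#'   allow the final leg.
#' @param gps_noise_km Isotropic positional jitter sd, km (default 0.5).
#' @param seed Integer RNG seed.
#' @return A `bird_scenario` list.
#' @export
bird_scenario <- function(species_label = "synthetic goose",
                          cue = c("melt75", "greenup", "melt25", "melt50",
                                  "melt100"),
                          true_lag_days = 2, lag_noise_sd = 1, n_tracks = 50,
                          fix_interval = 2, stopover_stay_days = 10,
                          gps_noise_km = 0.5, seed = 1L) {
  cue <- match.arg(cue)
  stopifnot(n_tracks >= 1, fix_interval > 0, lag_noise_sd >= 0,
            gps_noise_km >= 0, stopover_stay_days >= 2)
  structure(list(species_label = species_label, cue = cue,
                 true_lag_days = true_lag_days, lag_noise_sd = lag_noise_sd,
                 n_tracks = as.integer(n_tracks),
                 fix_interval = fix_interval,
                 stopover_stay_days = stopover_stay_days,
                 gps_noise_km = gps_noise_km, seed = as.integer(seed)),
            class = "bird_scenario")
}

round_half_up <- function(x) floor(x + 0.5)

# timestamps are generated on a UTC+8 civil-time grid (the study region's
# zone) and stored as UTC
local_day_hour_to_utc <- function(day, hour, year = 2021) {
  origin <- as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC")
  origin + (day - 1) * 86400 + hour * 3600 - 8 * 3600
}

#' Simulate migrating bird tracks with known ground truth
#'
#' For every track: a stopover pixel is drawn from the southern third of the
#' resource grid and a breeding pixel from the northern third; arrival days
#' follow the scenario's cue + lag + noise rule; the wintering site sits
#' ~900 km south of the grid. Fixes are emitted on a `fix_interval`-hour
#' UTC+8 civil-time grid with isotropic Gaussian positional jitter, covering
#' a window from shortly before winter departure to shortly after breeding
#' arrival (3 travel days winter to stopover, 2 stopover to breeding, with
#' linearly interpolated transit fixes). Pixels whose cue date is undefined
#' are redrawn (counted in `n_regenerated`).
#'
#' @param scen a [bird_scenario()].
#' @param surfaces a `resource_stack` of per-pixel resource dates (typically
#'   the generator truth; retrieval output works equally).
#' @param landscape a `landcover_grid` on the same grid.
#' @param fixes If `FALSE`, skip fix generation and return only the truth
#'   table (fast path for estimator studies).
#' @return list with `tracks` (data.frame bird_id, year, track_id,
#'   timestamp UTC, lon, lat), `truth` (data.frame track_id, site_id, role,
#'   lat, lon, cue, cue_date, true_arrival, departure_day) and
#'   `n_regenerated`.
#' @export
gen_tracks <- function(scen, surfaces, landscape, fixes = TRUE) {
  stopifnot(inherits(scen, "bird_scenario"),
            inherits(surfaces, "resource_stack"))
  set.seed(scen$seed)
  nr <- length(surfaces$lat); nc <- length(surfaces$lon)
  stop_rows <- seq_len(max(1, floor(nr / 3)))
  breed_rows <- seq(min(nr, ceiling(2 * nr / 3)), nr)
  cue_map <- surfaces$maps[[scen$cue]]
  n_regen <- 0L
  draw_pixel <- function(rows) {
    for (i in 1:50) {
      r <- sample(rows, 1); cc <- sample(nc, 1)
      if (!is.na(cue_map[r, cc])) return(c(r, cc))
      n_regen <<- n_regen + 1L
    }
    stop("could not find a pixel with a defined cue date")
  }
  year <- 2021L
  truth <- vector("list", scen$n_tracks)
  track_fixes <- vector("list", scen$n_tracks)
  for (i in seq_len(scen$n_tracks)) {
    repeat {
      ps <- draw_pixel(stop_rows); pb <- draw_pixel(breed_rows)
      arr_s <- round_half_up(cue_map[ps[1], ps[2]] + scen$true_lag_days +
                               stats::rnorm(1, 0, scen$lag_noise_sd))
      arr_b <- round_half_up(cue_map[pb[1], pb[2]] + scen$true_lag_days +
                               stats::rnorm(1, 0, scen$lag_noise_sd))
      # room for the minimum stay + 2 travel days, inside the year
      if (arr_b >= arr_s + scen$stopover_stay_days + 2 && arr_s >= 12 &&
            arr_b <= 206) break
      n_regen <- n_regen + 1L
    }
    dep_s <- arr_b - 3
    site_s <- c(lat = surfaces$lat[ps[1]], lon = surfaces$lon[ps[2]])
    site_b <- c(lat = surfaces$lat[pb[1]], lon = surfaces$lon[pb[2]])
    site_w <- c(lat = surfaces$lat[1] - 8 + stats::rnorm(1, 0, 0.2),
                lon = mean(surfaces$lon) + stats::rnorm(1, 0, 0.3))
    dep_w <- arr_s - 4        # 3 full travel days in between
    start_w <- max(1, dep_w - 5)
    end_b <- min(211, arr_b + 5)
    tid <- sprintf("bird%03d_%d", i, year)
    truth[[i]] <- data.frame(
      track_id = tid,
      site_id = paste0(tid, "_s", 1:3),
      role = c("winter", "stopover", "breeding"),
      lat = c(site_w["lat"], site_s["lat"], site_b["lat"]),
      lon = c(site_w["lon"], site_s["lon"], site_b["lon"]),
      cue = scen$cue,
      cue_date = c(NA, cue_map[ps[1], ps[2]], cue_map[pb[1], pb[2]]),
      true_arrival = c(start_w, arr_s, arr_b),
      departure_day = c(dep_w, dep_s, end_b),
      row.names = NULL)
    if (fixes) {
      seg <- function(day_from, day_to, p_from, p_to) {
        hours <- seq(0, 24 - scen$fix_interval, by = scen$fix_interval)
        dd <- rep(day_from:day_to, each = length(hours))
        hh <- rep(hours, day_to - day_from + 1)
        frac <- if (day_to > day_from) {
          ((dd - day_from) * 24 + hh) / ((day_to - day_from) * 24 + 24)
        } else rep(0, length(dd))
        lat <- p_from["lat"] + frac * (p_to["lat"] - p_from["lat"])
        lon <- p_from["lon"] + frac * (p_to["lon"] - p_from["lon"])
        jit <- km_to_deg(stats::rnorm(length(dd), 0, scen$gps_noise_km),
                         stats::rnorm(length(dd), 0, scen$gps_noise_km),
                         mean(lat))
        data.frame(day = dd, hour = hh, lon = lon + jit$dlon,
                   lat = lat + jit$dlat)
      }
      # transit legs stop 60 km short of each residency centroid so the
      # 50-km residency radius never captures en-route fixes
      pullback <- function(p_from, p_to, km = 60) {
        gap <- haversine_km(p_from["lon"], p_from["lat"],
                            p_to["lon"], p_to["lat"])
        if (gap < 2.5 * km) return(list(a = p_from, b = p_to))
        f1 <- km / gap; f2 <- 1 - km / gap
        mix <- function(f) c(lat = unname(p_from["lat"] +
                                            f * (p_to["lat"] - p_from["lat"])),
                             lon = unname(p_from["lon"] +
                                            f * (p_to["lon"] - p_from["lon"])))
        list(a = mix(f1), b = mix(f2))
      }
      leg1 <- pullback(site_w, site_s)
      leg2 <- pullback(site_s, site_b)
      fx <- rbind(
        seg(start_w, dep_w, site_w, site_w),
        seg(dep_w + 1, arr_s - 1, leg1$a, leg1$b),   # transit
        seg(arr_s, dep_s, site_s, site_s),
        seg(dep_s + 1, arr_b - 1, leg2$a, leg2$b),   # transit
        seg(arr_b, end_b, site_b, site_b))
      track_fixes[[i]] <- data.frame(
        bird_id = sprintf("bird%03d", i), year = year, track_id = tid,
        timestamp = local_day_hour_to_utc(fx$day, fx$hour, year),
        lon = fx$lon, lat = fx$lat)
    }
  }
  list(tracks = if (fixes) do.call(rbind, track_fixes) else NULL,
       truth = do.call(rbind, truth), n_regenerated = n_regen)
}

#' Turn a generator truth table into a sites table
#'
#' Fast path for estimator studies: bypasses fix-level segmentation and
#' yields the same sites frame that [segment_sites()] recovers.
#'
#' @param truth the `truth` element of [gen_tracks()] output.
#' @return data.frame with the [segment_sites()] site columns.
#' @export
sites_from_truth <- function(truth) {
  data.frame(track_id = truth$track_id, site_id = truth$site_id,
             role = truth$role, lat = truth$lat, lon = truth$lon,
             arrival_day = truth$true_arrival,
             departure_day = truth$departure_day,
             stay_days = truth$departure_day - truth$true_arrival + 1)
}

#' Write tracks / truth tables as CSV
#'
#' Tracks serialise with ISO-8601 UTC timestamps; truth tables serialise
#' verbatim so downstream recovery tests read ground truth only from file.
#'
#' @param x data.frame (`tracks` or `truth` element of [gen_tracks()]).
#' @param path file path.
#' @export
write_tracks_csv <- function(x, path) {
  x$timestamp <- format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  x <- utils::read.csv(path)
  x$timestamp <- as.POSIXct(x$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
  x
}
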