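#' Solar day/night labelling of GPS fixes
#'
#' Labels each fix `day` or `night` using the NOAA solar-position
#' algorithm (fractional-year Fourier expansions of the equation of time and
#' solar declination, zenith 90.833 degrees for sunrise/sunset). Waterfowl
#' forage mostly in daylight, so downstream habitat-use summaries are
#' restricted to daytime fixes; following the tracking literature, "day"
#' extends from one hour before sunrise to one hour after sunset.
#'
#' Under polar day (the sun never sets at that latitude and date) every fix
#' is `day`; under polar night every fix is `night`.
#'
#' @param fixes data.frame with columns `timestamp` (POSIXct, UTC), `lon`,
#'   `lat` in decimal degrees.
#' @param buffer_hours Hours added on either side of the sunrise--sunset
#'   interval (default 1).
#' @return `fixes` with a `daynight` factor column (`"day"`/`"night"`).
#' @export
label_day_night <- function(fixes, buffer_hours = 1) {
  stopifnot(all(c("timestamp", "lon", "lat") %in% names(fixes)))
  tt <- as.POSIXlt(fixes$timestamp, tz = "UTC")
  doy <- tt$yday + 1
  minute_utc <- tt$hour * 60 + tt$min + tt$sec / 60
  sol <- noaa_sun_geometry(doy, fixes$lat)
  # minutes from local solar noon, wrapped to (-720, 720]
  noon <- 720 - 4 * fixes$lon - sol$eqtime
  diff <- ((minute_utc - noon + 720) %% 1440) - 720
  half_day <- 4 * sol$ha_deg + buffer_hours * 60
  day <- abs(diff) <= half_day
  day[sol$polar == "day"] <- TRUE
  day[sol$polar == "night"] <- FALSE
  fixes$daynight <- factor(ifelse(day, "day", "night"),
                           levels = c("day", "night"))
  fixes
}

#' Sunrise and sunset (UTC) by the NOAA algorithm
#'
#' @param doy Day of year (1 = 1 Jan).
#' @param lat,lon Decimal degrees.
#' @return data.frame with `sunrise_utc`, `sunset_utc` (minutes after 00:00
#'   UTC; `NA` with `polar` set under polar day/night) and `polar`
#'   (`"none"`, `"day"` or `"night"`).
#' @export
sunrise_sunset <- function(doy, lat, lon) {
  sol <- noaa_sun_geometry(doy, lat)
  sunrise <- 720 - 4 * (lon + sol$ha_deg) - sol$eqtime
  sunset <- 720 - 4 * (lon - sol$ha_deg) - sol$eqtime
  sunrise[sol$polar != "none"] <- NA_real_
  sunset[sol$polar != "none"] <- NA_real_
  data.frame(sunrise_utc = sunrise, sunset_utc = sunset, polar = sol$polar)
}

# Equation of time (minutes), solar declination (rad) and the sunrise hour
# angle (degrees) at zenith 90.833 deg. NOAA's Fourier-series formulation;
# fractional year evaluated at solar noon.
noaa_sun_geometry <- function(doy, lat) {
  g <- 2 * pi / 365 * (doy - 1)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  latr <- lat * pi / 180
  cos_ha <- cos(90.833 * pi / 180) / (cos(latr) * cos(decl)) -
    tan(latr) * tan(decl)
  polar <- rep("none", length(cos_ha))
  polar[cos_ha < -1] <- "day"    # sun never sets
  polar[cos_ha > 1] <- "night"   # sun never rises
  ha <- acos(pmin(1, pmax(-1, cos_ha))) * 180 / pi
  list(eqtime = eqtime, decl = decl, ha_deg = ha, polar = polar)
}
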