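#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371 km, the conventional
#' mean Earth radius used for migration-distance bookkeeping.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees. Vectorised;
#'   arguments are recycled to a common length.
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_km(0, 0, 1, 0)  # ~111.19 km along the equator
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dp <- (lat2 - lat1) * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# Kilometre offsets in a local tangent plane -> degree offsets at a
# reference latitude. One degree of latitude is taken as 110.574 km and one
# degree of longitude as 111.320 * cos(lat) km.
km_to_deg <- function(dx_km, dy_km, lat) {
  list(
    dlon = dx_km / (111.320 * cos(lat * pi / 180)),
    dlat = dy_km / 110.574
  )
}
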