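#' The seven aggregated land-cover classes
#'
#' Fine land-cover products are aggregated to seven types for habitat-use
#' analysis: grassland, farmland, water, wetland, forest, shrubland and
#' "other" (barren land, snow and ice, built-up areas).
#' @export
LANDCOVER_CLASSES <- c("grassland", "farmland", "water", "wetland",
                       "forest", "shrubland", "other")

#' Landscape specification for the synthetic generator
#'
#' @param n_rows,n_cols Grid dimensions (rows run south to north).
#' @param pixel_km Pixel edge length in kilometres.
#' @param lat_origin,lon_origin Degrees; the south-west corner of the grid.
#' @param class_weights Named probabilities over the seven classes in
#'   [LANDCOVER_CLASSES]; must sum to 1. Missing classes get weight 0.
#' @param seed Integer RNG seed.
#' @return A `landscape_spec` list.
#' @export
landscape_spec <- function(n_rows, n_cols, pixel_km, lat_origin, lon_origin,
                           class_weights, seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, pixel_km > 0)
  w <- setNames(numeric(length(LANDCOVER_CLASSES)), LANDCOVER_CLASSES)
  unknown <- setdiff(names(class_weights), LANDCOVER_CLASSES)
  if (length(unknown))
    stop("unknown land-cover class(es): ", paste(unknown, collapse = ", "))
  w[names(class_weights)] <- unlist(class_weights)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("class_weights must be non-negative and sum to 1")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pixel_km = pixel_km, lat_origin = lat_origin,
                 lon_origin = lon_origin, class_weights = w,
                 seed = as.integer(seed)),
            class = "landscape_spec")
}

# row/column centre coordinates of a grid defined by a landscape_spec
grid_georef <- function(spec) {
  dlat <- spec$pixel_km / 110.574
  dlon <- spec$pixel_km / (111.320 * cos(spec$lat_origin * pi / 180))
  list(lat = spec$lat_origin + (seq_len(spec$n_rows) - 0.5) * dlat,
       lon = spec$lon_origin + (seq_len(spec$n_cols) - 0.5) * dlon)
}

#' Generate a categorical land-cover grid
#'
#' Each pixel is drawn independently from `class_weights`; deterministic for
#' a fixed `seed`.
#'
#' @param spec a [landscape_spec()].
#' @return A `landcover_grid`: character matrix (`n_rows` x `n_cols`) of the
#'   seven class labels with `lat`/`lon` attributes.
#' @export
gen_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(spec$seed)
  classes <- sample(LANDCOVER_CLASSES, spec$n_rows * spec$n_cols,
                    replace = TRUE, prob = spec$class_weights)
  g <- matrix(classes, nrow = spec$n_rows, ncol = spec$n_cols)
  geo <- grid_georef(spec)
  structure(g, lat = geo$lat, lon = geo$lon, pixel_km = spec$pixel_km,
            class = c("landcover_grid", class(g)))
}

#' @export
print.landcover_grid <- function(x, ...) {
  cat(sprintf("<landcover_grid> %d x %d pixels (%.1f km)\n",
              nrow(x), ncol(x), attr(x, "pixel_km")))
  print(round(prop.table(table(factor(c(unclass(x)), LANDCOVER_CLASSES))), 3))
  invisible(x)
}

# nearest pixel (row, col) of a grid / raster_series georeference for given
# lon/lat. Returns NA for points outside the grid extent (half-pixel margin).
locate_pixel <- function(lon, lat, grid_lat, grid_lon, pixel_km) {
  dlat <- if (length(grid_lat) > 1) diff(grid_lat[1:2]) else pixel_km / 110.574
  dlon <- if (length(grid_lon) > 1) diff(grid_lon[1:2]) else pixel_km / 111.320
  row <- round((lat - grid_lat[1]) / dlat) + 1
  col <- round((lon - grid_lon[1]) / dlon) + 1
  row[row < 1 | row > length(grid_lat)] <- NA_integer_
  col[col < 1 | col > length(grid_lon)] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}
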