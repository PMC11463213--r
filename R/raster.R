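#' Gridded time-series container
#'
#' A minimal in-memory raster time series: a 3-d numeric array with named
#' dimensions `(day, row, col)` plus georeference vectors giving the centre
#' latitude of each row and centre longitude of each column. This is the
#' layout the generators emit and the phenology/snowmelt retrievals consume;
#' `write_raster_series()` serialises it to a portable long-format CSV.
#'
#' @param values numeric array, dim `c(length(days), n_row, n_col)`.
#' @param days integer vector of Julian days (1 = 1 Jan).
#' @param lat,lon numeric vectors of row-centre latitudes / column-centre
#'   longitudes, degrees.
#' @param kind free-text tag, e.g. `"evi"` or `"snow"`.
#' @return An object of class `raster_series`.
#' @export
raster_series <- function(values, days, lat, lon, kind = "series") {
  stopifnot(is.array(values), length(dim(values)) == 3,
            dim(values)[1] == length(days),
            dim(values)[2] == length(lat),
            dim(values)[3] == length(lon))
  dimnames(values) <- NULL
  structure(list(values = values, days = as.integer(days),
                 lat = lat, lon = lon, kind = kind),
            class = "raster_series")
}

#' @export
print.raster_series <- function(x, ...) {
  cat(sprintf("<raster_series '%s'> %d days x %d rows x %d cols\n",
              x$kind, length(x$days), length(x$lat), length(x$lon)))
  cat(sprintf("  days %d..%d; lat %.3f..%.3f; lon %.3f..%.3f\n",
              min(x$days), max(x$days), min(x$lat), max(x$lat),
              min(x$lon), max(x$lon)))
  invisible(x)
}

# extract the time series of one pixel
pixel_series <- function(x, row, col) x$values[, row, col]

#' Write / read a raster series as long-format CSV
#'
#' Layout: comment header lines (`#key=value`) carrying the kind and the
#' georeference, then columns `day,row,col,value`. Plain text and
#' NetCDF-convertible (named dims day/row/col).
#'
#' @param x a `raster_series`.
#' @param path file path.
#' @return `read_raster_series` returns a `raster_series`.
#' @export
write_raster_series <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#kind=%s", x$kind),
               sprintf("#days=%s", paste(x$days, collapse = ";")),
               sprintf("#lat=%s", paste(format(x$lat, digits = 10), collapse = ";")),
               sprintf("#lon=%s", paste(format(x$lon, digits = 10), collapse = ";"))),
             con)
  idx <- expand.grid(day_i = seq_along(x$days), row = seq_along(x$lat),
                     col = seq_along(x$lon))
  df <- data.frame(day = x$days[idx$day_i], row = idx$row, col = idx$col,
                   value = as.vector(x$values))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_series
#' @export
read_raster_series <- function(path) {
  hdr <- readLines(path, n = 4)
  stopifnot(startsWith(hdr[1], "#kind="))
  val <- function(line) sub("^#[a-z]+=", "", line)
  days <- as.integer(strsplit(val(hdr[2]), ";")[[1]])
  lat <- as.numeric(strsplit(val(hdr[3]), ";")[[1]])
  lon <- as.numeric(strsplit(val(hdr[4]), ";")[[1]])
  df <- utils::read.csv(path, skip = 4)
  arr <- array(NA_real_, dim = c(length(days), length(lat), length(lon)))
  arr[cbind(match(df$day, days), df$row, df$col)] <- df$value
  raster_series(arr, days, lat, lon, kind = val(hdr[1]))
}
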