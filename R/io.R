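#' Write / read a station table as CSV
#'
#' Station tables have columns `station_id`, `lon`, `lat`, `elev`, `date`
#' (ISO-8601), `mt`, `rh`.
#'
#' @param series Data frame with at least `station_id`, `date`, `mt`, `rh`;
#'   `lon`/`lat`/`elev` filled with `NA` when absent.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_station_csv <- function(series, path) {
  for (col in c("lon", "lat", "elev")) {
    if (is.null(series[[col]])) series[[col]] <- NA_real_
  }
  out <- series[, c("station_id", "lon", "lat", "elev", "date", "mt", "rh")]
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_station_csv
#' @export
read_station_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  df
}

#' Write / read a climate grid as long-format CSV
#'
#' One row per (date, pixel): `date`, `lon`, `lat`, `mt`, `rh`. The reader
#' reconstructs the `(time, y, x)` arrays from the coordinate and date
#' columns, which must form a complete regular grid.
#'
#' @param grid A [climate_grid()].
#' @param path CSV path.
#' @return `path` invisibly (writer); a [climate_grid()] (reader).
#' @export
write_climate_csv <- function(grid, path) {
  stopifnot(inherits(grid, "climate_grid"))
  d <- dim(grid$mt)
  df <- data.frame(
    date = rep(format(grid$dates, "%Y-%m-%d"), times = d[2L] * d[3L]),
    lon = rep(rep(grid$lon, each = d[1L] * d[2L])),
    lat = rep(rep(grid$lat, each = d[1L]), times = d[3L]),
    mt = as.vector(grid$mt),
    rh = as.vector(grid$rh))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climate_csv
#' @export
read_climate_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  dates <- sort(unique(as.Date(df$date)))
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  nt <- length(dates); ny <- length(lat); nx <- length(lon)
  if (nrow(df) != nt * ny * nx) {
    stop("incomplete grid: rows != n_dates * n_lat * n_lon", call. = FALSE)
  }
  ti <- match(as.Date(df$date), dates)
  yi <- match(df$lat, lat)
  xi <- match(df$lon, lon)
  mt <- array(NA_real_, c(nt, ny, nx))
  rh <- array(NA_real_, c(nt, ny, nx))
  idx <- cbind(ti, yi, xi)
  mt[idx] <- df$mt
  rh[idx] <- df$rh
  climate_grid(mt, rh, dates, lon, lat)
}

#' Write detected events or a zone table as CSV
#'
#' Thin wrapper kept for interface symmetry.
#'
#' @param table Data frame (events from [detect_events_grid()], zone table
#'   from [zonal_statistics()], ...).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
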