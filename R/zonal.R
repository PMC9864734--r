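#' Read zone polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon/MultiPolygon features. Each feature
#' becomes one zone; the zone name is taken from the first of the `name`,
#' `NAME` or `id` properties, falling back to `zone<i>`. Only outer rings are
#' used (holes are rare in administrative zoning at this resolution and are
#' ignored).
#'
#' @param path Path to a GeoJSON file.
#' @return Named list of boundary matrices (two columns, lon/lat; multiple
#'   rings separated by `NA` rows), suitable for [zonal_statistics()].
#' @export
read_zones_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection",
                                 call. = FALSE)
  ring_matrix <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  }
  zones <- list()
  for (i in seq_along(gj$features)) {
    f <- gj$features[[i]]
    nm <- f$properties$name %||% f$properties$NAME %||% f$id %||%
      paste0("zone", i)
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, function(po) po[[1]]),
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    )
    mats <- lapply(rings, ring_matrix)
    bnd <- mats[[1]]
    for (m in mats[-1]) bnd <- rbind(bnd, c(NA, NA), m)
    zones[[as.character(nm)]] <- bnd
  }
  zones
}

#' Zonal hazard statistics and ranking
#'
#' For each zone polygon: the mean AH over covered valid pixels, the OLS
#' slope and p of the zone-mean annual hazard over years, and descending
#' ranks by AH and by slope. A pixel belongs to a zone when its centre falls
#' inside the polygon (point-in-polygon via [mgcv::in.out()]). Zones covering
#' no valid pixel are flagged and excluded from the rankings; rank ties are
#' broken by zone order in `zones`.
#'
#' @param ah `ny x nx` matrix of average hazard.
#' @param hazard `(n_years, ny, nx)` annual hazard stack.
#' @param years Year axis of `hazard`.
#' @param lon,lat Pixel-centre coordinate vectors (length `nx`, `ny`).
#' @param zones Named list of boundary matrices (see
#'   [read_zones_geojson()]), or a single matrix for one zone.
#' @param alpha Significance level for the trend flag.
#' @return Data frame (`zone`, `n_pixels`, `mean_ah`, `slope`, `p`,
#'   `significant`, `rank_ah`, `rank_slope`), one row per zone.
#' @export
zonal_statistics <- function(ah, hazard, years, lon, lat, zones,
                             alpha = 0.05) {
  if (is.matrix(zones)) zones <- list(zone1 = zones)
  if (length(zones) == 0L) stop("empty zone set", call. = FALSE)
  if (is.null(names(zones))) names(zones) <- paste0("zone", seq_along(zones))
  d <- dim(hazard)
  if (!all(dim(ah) == d[2:3])) {
    stop("`ah` and `hazard` shapes do not match", call. = FALSE)
  }
  centres <- cbind(lon = rep(lon, each = length(lat)),
                   lat = rep(lat, times = length(lon)))  # matches [y, x] order
  H <- matrix(hazard, nrow = d[1L])         # years x pixels
  res <- data.frame(zone = names(zones), n_pixels = 0L,
                    mean_ah = NA_real_, slope = NA_real_, p = NA_real_,
                    significant = NA)
  for (i in seq_along(zones)) {
    inside <- mgcv::in.out(zones[[i]], centres)
    inside <- inside & is.finite(as.vector(ah))
    res$n_pixels[i] <- sum(inside)
    if (!any(inside)) next
    res$mean_ah[i] <- mean(as.vector(ah)[inside])
    zm <- rowMeans(H[, inside, drop = FALSE])
    tr <- linear_trend(zm, years, alpha)
    res$slope[i] <- tr$slope
    res$p[i] <- tr$p
    res$significant[i] <- isTRUE(tr$significant)
  }
  valid <- res$n_pixels > 0L
  rank_desc <- function(v) {
    r <- rep(NA_integer_, length(v))
    ord <- order(-v[valid], seq_len(sum(valid)))
    r[which(valid)[ord]] <- seq_len(sum(valid))
    r
  }
  res$rank_ah <- rank_desc(res$mean_ah)
  res$rank_slope <- rank_desc(res$slope)
  res
}
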