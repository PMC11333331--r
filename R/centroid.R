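#' Binary suitable-range mask
#'
#' Cells with suitability at or above the threshold (and valid data) form
#' the suitable range; the default cut-off is the configured total-suitable
#' threshold 0.04.
#'
#' @param suitability \linkS4class{RasterGrid} of suitabilities in [0, 1].
#' @param threshold cut-off in [0, 1]; a cell exactly at the threshold is
#'   included (\eqn{p \ge} threshold).
#' @return logical matrix mask.
#' @export
binarizeSuitability <- function(suitability, threshold = 0.04) {
  if (threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  v <- suitability@values
  !is.na(v) & v >= threshold
}

#' Area-weighted centroid of a masked range
#'
#' Longitude/latitude means over the masked cell centers, weighted by the
#' true (cosine-of-latitude) cell areas; an unweighted mode is available for
#' comparison.
#'
#' @param mask logical matrix over the grid.
#' @param grid the \linkS4class{RasterGrid} the mask lives on.
#' @param weighted area-weight the cells (default) or not.
#' @return named numeric \code{c(lon, lat)}.
#' @export
centroidOfMask <- function(mask, grid, weighted = TRUE) {
  idx <- which(mask)
  if (!length(idx)) stop("mask is empty: no suitable range", call. = FALSE)
  d <- dim(grid@values)
  row <- (idx - 1L) %% d[1L] + 1L
  col <- (idx - 1L) %/% d[1L] + 1L
  ctr <- .cellCenter(grid, row, col)
  w <- if (weighted) cellAreaKm2(grid, row) else rep(1, length(idx))
  c(lon = sum(w * ctr$lon) / sum(w), lat = sum(w * ctr$lat) / sum(w))
}

#' Great-circle distance (haversine)
#'
#' Haversine formula on a spherical Earth of radius 6371.0 km — the radius
#' that reproduces published centroid-migration distances to their printed
#' precision.
#'
#' @param a,b numeric \code{c(lon, lat)} in decimal degrees.
#' @return distance in km.
#' @examples
#' haversineKm(c(0, 0), c(1, 0)) # one equatorial degree, ~111.195 km
#' @export
haversineKm <- function(a, b) {
  r <- pi / 180
  dlat <- (b[[2]] - a[[2]]) * r
  dlon <- (b[[1]] - a[[1]]) * r
  h <- sin(dlat / 2)^2 +
    cos(a[[2]] * r) * cos(b[[2]] * r) * sin(dlon / 2)^2
  2 * 6371.0 * asin(pmin(1, sqrt(h)))
}

#' Initial great-circle bearing
#'
#' @inheritParams haversineKm
#' @return azimuth in degrees clockwise from north, in [0, 360); \code{NA}
#'   for identical points.
#' @export
bearingDeg <- function(a, b) {
  if (isTRUE(all.equal(as.numeric(a), as.numeric(b)))) return(NA_real_)
  r <- pi / 180
  dlon <- (b[[1]] - a[[1]]) * r
  y <- sin(dlon) * cos(b[[2]] * r)
  x <- cos(a[[2]] * r) * sin(b[[2]] * r) -
    sin(a[[2]] * r) * cos(b[[2]] * r) * cos(dlon)
  (atan2(y, x) / r) %% 360
}

#' Centroid-migration table
#'
#' One row per scenario centroid: coordinates, haversine distance from the
#' baseline centroid (distances radiate from the baseline; they are not
#' chained between periods), and the initial bearing. A scenario identical
#' to the baseline reports distance 0 and an undefined (\code{NA}) bearing.
#'
#' @param baseline named numeric \code{c(lon, lat)} of the baseline
#'   (current) centroid.
#' @param scenarios named list of \code{c(lon, lat)} scenario centroids.
#' @return data.frame \code{scenario}, \code{lon}, \code{lat},
#'   \code{distance_km}, \code{bearing_deg}.
#' @export
migrationTable <- function(baseline, scenarios) {
  if (length(baseline) != 2L || any(!is.finite(baseline)))
    stop("baseline centroid must be a finite (lon, lat) pair",
         call. = FALSE)
  rows <- lapply(names(scenarios), function(nm) {
    sc <- scenarios[[nm]]
    data.frame(scenario = nm, lon = sc[[1]], lat = sc[[2]],
               distance_km = haversineKm(baseline, sc),
               bearing_deg = bearingDeg(baseline, sc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
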