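#' Great-circle distance on a spherical Earth
#'
#' Computes the shortest ("great circle") distance between points on a
#' spherical approximation of the Earth, in kilometres. Coordinates are
#' geographic latitude/longitude in decimal degrees (WGS84). The formula is
#' the numerically stable `atan2` form of the spherical law of cosines, so it
#' behaves well for both antipodal and very close points.
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param lat1,lon1 Latitude and longitude of the first point(s), decimal
#'   degrees.
#' @param lat2,lon2 Latitude and longitude of the second point(s), decimal
#'   degrees.
#' @param radius Sphere radius in kilometres. The default, 6378.137 km, is the
#'   WGS84 equatorial radius used by the common spherical-distance routines in
#'   geographic software.
#' @return Numeric vector of distances in km.
#' @examples
#' gc_distance(0, 0, 0, 1)   # ~111.32 km along the equator
#' @export
gc_distance <- function(lat1, lon1, lat2, lon2, radius = 6378.137) {
  check_latlon(lat1, lon1)
  check_latlon(lat2, lon2)
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  num <- sqrt((cos(p2) * sin(dl))^2 + (cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl))^2)
  den <- sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)
  radius * atan2(num, den)
}

#' Final bearing of a great-circle arc
#'
#' The bearing of the arc from the first point as it arrives at the second
#' point, measured clockwise from north in degrees `[0, 360)`. On the sphere
#' the bearing changes continuously along an arc; the final bearing is the
#' reverse of the initial bearing taken from the destination.
#'
#' @inheritParams gc_distance
#' @return Numeric vector of bearings in degrees, `NA` for coincident points.
#' @examples
#' final_bearing(0, 0, 0, 10)  # 90: due east along the equator
#' @export
final_bearing <- function(lat1, lon1, lat2, lon2) {
  check_latlon(lat1, lon1)
  check_latlon(lat2, lon2)
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)
  same <- lat1 == lat2 & lon1 == lon2
  if (all(same)) stop("final_bearing() is undefined for coincident points", call. = FALSE)
  # final bearing = initial bearing of the reversed arc, turned 180 degrees
  p1 <- lat2 * pi / 180
  p2 <- lat1 * pi / 180
  dl <- (lon1 - lon2) * pi / 180
  theta <- atan2(sin(dl) * cos(p2), cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl))
  b <- (theta * 180 / pi + 180) %% 360
  b[same] <- NA_real_
  b
}

#' Fold a bearing into a direction class on `[0, 180)`
#'
#' A lag and its reverse belong to the same direction for variography, so
#' bearings are folded modulo 180 degrees.
#'
#' @param bearing Bearings in degrees.
#' @return Bearings folded to `[0, 180)`.
#' @export
fold_bearing <- function(bearing) bearing %% 180

#' All pairwise great-circle lags between locations
#'
#' Builds the `n(n-1)/2` unordered pairs of a set of locations, with the
#' great-circle distance and the folded arrival bearing of each pair. This is
#' the lag table underlying empirical variogram estimation.
#'
#' @param data Data frame with columns `lat` and `lon` (or `mean_lat` and
#'   `mean_lon`, as produced by [aggregate_by_ea()]), decimal degrees.
#' @param radius Sphere radius in km.
#' @return Tibble with columns `i`, `j` (row indices of the pair), `distance`
#'   (km) and `bearing` (degrees folded to `[0, 180)`; `NA` with a warning for
#'   duplicate coordinates, where the bearing is undefined).
#' @export
pairwise_lags <- function(data, radius = 6378.137) {
  xy <- latlon_cols(data)
  n <- nrow(xy)
  if (n < 2) stop("need at least 2 locations to form pairs", call. = FALSE)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  d <- gc_distance(xy$lat[i], xy$lon[i], xy$lat[j], xy$lon[j], radius = radius)
  dup <- xy$lat[i] == xy$lat[j] & xy$lon[i] == xy$lon[j]
  b <- rep(NA_real_, length(i))
  if (any(!dup)) {
    b[!dup] <- fold_bearing(final_bearing(xy$lat[i[!dup]], xy$lon[i[!dup]],
                                          xy$lat[j[!dup]], xy$lon[j[!dup]]))
  }
  if (any(dup)) {
    warning(sum(dup), " pair(s) of duplicate coordinates: distance 0, bearing undefined",
            call. = FALSE)
  }
  tibble::tibble(i = i, j = j, distance = d, bearing = b)
}

# shared validation --------------------------------------------------------

check_latlon <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("latitude/longitude must be finite", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]", call. = FALSE)
  invisible(TRUE)
}

latlon_cols <- function(data) {
  nm <- names(data)
  if (all(c("lat", "lon") %in% nm)) {
    tibble::tibble(lat = data$lat, lon = data$lon)
  } else if (all(c("mean_lat", "mean_lon") %in% nm)) {
    tibble::tibble(lat = data$mean_lat, lon = data$mean_lon)
  } else {
    stop("data must have lat/lon or mean_lat/mean_lon columns", call. = FALSE)
  }
}
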