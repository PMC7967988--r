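#' Great-circle distance between points
#'
#' Haversine distance on a spherical earth of radius 6371 km. All inputs are
#' decimal degrees (WGS84 coordinates treated as spherical); vectorised over
#' coordinates. Ellipsoidal geodesics over the European flyway differ from
#' these spherical distances by well under 0.5%, below any threshold used by
#' the event and site detectors.
#'
#' @param lat1,lon1 Coordinates of the first point, decimal degrees.
#' @param lat2,lon2 Coordinates of the second point, decimal degrees.
#' @return Distance in kilometres (numeric vector).
#' @examples
#' great_circle_km(0, 0, 0, 1)   # one degree of longitude at the equator
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  p <- pi / 180
  a <- sin((lat2 - lat1) * p / 2)^2 +
    cos(lat1 * p) * cos(lat2 * p) * sin((lon2 - lon1) * p / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat) | !is.finite(lon)) ||
      any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stop("invalid coordinates: lat must be in [-90, 90], lon in [-180, 180]",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Initial great-circle bearing from one point towards another
#'
#' @inheritParams great_circle_km
#' @return Bearing in degrees clockwise from north, in \[0, 360).
#' @export
bearing_deg <- function(lat1, lon1, lat2, lon2) {
  p <- pi / 180
  dl <- (lon2 - lon1) * p
  y <- sin(dl) * cos(lat2 * p)
  x <- cos(lat1 * p) * sin(lat2 * p) - sin(lat1 * p) * cos(lat2 * p) * cos(dl)
  (atan2(y, x) / p) %% 360
}

# Destination point along a great circle: start, initial bearing, distance.
# Used by the track simulator to step positions; spherical earth R = 6371 km.
destination_point <- function(lat, lon, bearing, dist_km) {
  p <- pi / 180
  d <- dist_km / 6371
  la1 <- lat * p
  br <- bearing * p
  la2 <- asin(sin(la1) * cos(d) + cos(la1) * sin(d) * cos(br))
  lo2 <- lon * p + atan2(sin(br) * sin(d) * cos(la1),
                         cos(d) - sin(la1) * sin(la2))
  list(lat = la2 / p, lon = ((lo2 / p + 540) %% 360) - 180)
}

#' Circular mean of directions
#'
#' Direction of the resultant vector of unit vectors, the standard circular
#' mean for wind directions and flight bearings. When the resultant length is
#' (numerically) zero the mean direction is undefined and `NA` is returned.
#'
#' @param deg Directions in degrees.
#' @param na.rm Drop missing values first.
#' @return Mean direction in degrees in \[0, 360), or `NA` if undefined.
#' @examples
#' circular_mean_deg(c(350, 10))  # 0, not 180
#' @export
circular_mean_deg <- function(deg, na.rm = FALSE) {
  if (na.rm) deg <- deg[!is.na(deg)]
  if (length(deg) == 0 || anyNA(deg)) return(NA_real_)
  p <- pi / 180
  s <- mean(sin(deg * p))
  c <- mean(cos(deg * p))
  if (sqrt(s^2 + c^2) < 1e-9) return(NA_real_)
  m <- (atan2(s, c) / p) %% 360
  if (m > 360 - 1e-9) 0 else m
}

#' Shortest angular difference between two directions
#'
#' @param a,b Directions in degrees.
#' @return Absolute shortest-arc difference in degrees, in \[0, 180\].
#' @export
circular_diff_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
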