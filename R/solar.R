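#' Sunrise and sunset times (NOAA solar position)
#'
#' Computes apparent sunrise and sunset in UTC for a date and location using
#' the NOAA solar calculator equations (solar zenith 90.833 degrees, i.e.
#' including standard atmospheric refraction and the solar disc radius).
#' Accuracy is within a few minutes of the NOAA reference for mid-latitudes,
#' far inside the one-minute cadence of the station records that are averaged
#' over the daylight window.
#'
#' @param date A `Date` (or something coercible to one).
#' @param lat,lon Location in decimal degrees. Latitudes poleward of 66.5
#'   degrees are refused: polar day/night makes the daylight window undefined.
#' @return A list with POSIXct `sunrise` and `sunset` (UTC).
#' @examples
#' sunrise_sunset(as.Date("2017-03-20"), 54.132, 8.877)
#' @export
sunrise_sunset <- function(date, lat, lon) {
  date <- as.Date(date)
  check_coords(lat, lon)
  if (abs(lat) >= 66.5) {
    stop("latitude ", lat, " is poleward of 66.5 degrees: polar day/night, ",
         "daylight window undefined", call. = FALSE)
  }
  jd <- as.numeric(date) + 2440587.5      # Julian day at 0h UT
  t <- (jd - 2451545.0) / 36525.0
  deg2rad <- pi / 180

  l0 <- (280.46646 + t * (36000.76983 + 0.0003032 * t)) %% 360
  m <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  ecc <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  c <- sin(m * deg2rad) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(2 * m * deg2rad) * (0.019993 - 0.000101 * t) +
    sin(3 * m * deg2rad) * 0.000289
  true_long <- l0 + c
  omega <- 125.04 - 1934.136 * t
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * deg2rad)
  e0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - t * 0.001813))) / 60) / 60
  e_corr <- e0 + 0.00256 * cos(omega * deg2rad)
  decl <- asin(sin(e_corr * deg2rad) * sin(app_long * deg2rad)) / deg2rad

  y <- tan(e_corr * deg2rad / 2)^2
  eqtime <- 4 / deg2rad * (
    y * sin(2 * l0 * deg2rad) -
      2 * ecc * sin(m * deg2rad) +
      4 * ecc * y * sin(m * deg2rad) * cos(2 * l0 * deg2rad) -
      0.5 * y^2 * sin(4 * l0 * deg2rad) -
      1.25 * ecc^2 * sin(2 * m * deg2rad))

  cos_ha <- cos(90.833 * deg2rad) / (cos(lat * deg2rad) * cos(decl * deg2rad)) -
    tan(lat * deg2rad) * tan(decl * deg2rad)
  if (any(abs(cos_ha) > 1)) {
    stop("sun does not rise or set on ", format(date), " at latitude ", lat,
         call. = FALSE)
  }
  ha <- acos(cos_ha) / deg2rad
  noon_min <- 720 - 4 * lon - eqtime
  midnight <- as.POSIXct(paste0(format(date), " 00:00:00"), tz = "UTC")
  list(sunrise = midnight + 60 * (noon_min - 4 * ha),
       sunset = midnight + 60 * (noon_min + 4 * ha))
}

# Solar elevation angle (degrees) at POSIXct instants, used for the synthetic
# clear-sky global-radiation curve. Same NOAA ephemeris as sunrise_sunset.
solar_elevation <- function(time, lat, lon) {
  jd <- as.numeric(time) / 86400 + 2440587.5
  t <- (jd - 2451545.0) / 36525.0
  deg2rad <- pi / 180
  l0 <- (280.46646 + t * (36000.76983 + 0.0003032 * t)) %% 360
  m <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  ecc <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  c <- sin(m * deg2rad) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(2 * m * deg2rad) * (0.019993 - 0.000101 * t) +
    sin(3 * m * deg2rad) * 0.000289
  app_long <- l0 + c - 0.00569 - 0.00478 * sin((125.04 - 1934.136 * t) * deg2rad)
  e_corr <- 23 + (26 + (21.448 - t * 46.815) / 60) / 60 +
    0.00256 * cos((125.04 - 1934.136 * t) * deg2rad)
  decl <- asin(sin(e_corr * deg2rad) * sin(app_long * deg2rad))
  y <- tan(e_corr * deg2rad / 2)^2
  eqtime <- 4 / deg2rad * (
    y * sin(2 * l0 * deg2rad) - 2 * ecc * sin(m * deg2rad) +
      4 * ecc * y * sin(m * deg2rad) * cos(2 * l0 * deg2rad) -
      0.5 * y^2 * sin(4 * l0 * deg2rad) - 1.25 * ecc^2 * sin(2 * m * deg2rad))
  min_of_day <- (as.numeric(time) %% 86400) / 60
  tst <- (min_of_day + eqtime + 4 * lon) %% 1440
  ha <- (tst / 4 - 180) * deg2rad
  lat_r <- lat * deg2rad
  asin(sin(lat_r) * sin(decl) + cos(lat_r) * cos(decl) * cos(ha)) / deg2rad
}
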