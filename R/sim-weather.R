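#' Simulate station and large-scale weather series
#'
#' Generates (a) a 1-min local weather-station table with the eight variables
#' recorded at the wintering site (temperature, wind speed, maximum wind
#' speed, wind direction, precipitation, global radiation, air pressure,
#' humidity) and (b) a daily large-scale table (temperature, pressure, u/v
#' surface wind components) for a single grid cell over the flyway.
#'
#' Every calendar date is simulated under its own seed derived from
#' `config$seed`, so the series for a date is identical whether that date is
#' generated alone or as part of a span; this is what makes
#' "same-date-in-previous-years" reference windows cheap. Wind direction
#' follows the meteorological convention (degrees FROM which the wind blows);
#' the large-scale components use the standard convention u = eastward,
#' v = northward, so `u = -speed * sin(dir)`, `v = -speed * cos(dir)`.
#' Dry days have exactly zero precipitation in every record, which exercises
#' the difference fallback of the contrast rule downstream.
#'
#' @param config A [sim_config()].
#' @param dates Optional vector of `Date`s to simulate. Default: every day of
#'   `config$years`.
#' @return A list with elements `station` (1-min tibble), `large_scale`
#'   (daily tibble) and `day_info` (per-day regime summary, including a
#'   `cloudless` flag used to pick training days for the cloudiness proxy).
#' @export
simulate_weather <- function(config, dates = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(dates)) {
    dates <- seq(as.Date(paste0(min(config$years), "-01-01")),
                 as.Date(paste0(max(config$years), "-12-31")), by = "day")
  }
  dates <- sort(unique(as.Date(dates)))
  ws <- config$wintering_site
  days <- purrr::map(dates, simulate_weather_day, config = config,
                     lat = ws[["lat"]], lon = ws[["lon"]])
  list(
    station = dplyr::bind_rows(purrr::map(days, "station")),
    large_scale = dplyr::bind_rows(purrr::map(days, "large_scale")),
    day_info = dplyr::bind_rows(purrr::map(days, "day_info"))
  )
}

simulate_weather_day <- function(date, config, lat, lon) {
  day_key <- as.integer(date)
  withr::with_seed(derive_seed(config$seed, paste0("wx", day_key)), {
    n <- 1440L
    ts <- as.POSIXct(paste0(format(date), " 00:00:00"), tz = "UTC") +
      60 * (seq_len(n) - 1L)
    doy <- as.integer(strftime(date, "%j", tz = "UTC"))

    wr <- config$wind_regime
    if (wr$type == "constant") {
      day_dir <- wr$dir %% 360
      day_speed <- wr$speed
      dir <- rep(day_dir, n)
      speed <- rep(day_speed, n)
    } else if (wr$type == "calm") {
      day_dir <- 0
      day_speed <- 0
      dir <- rep(0, n)
      speed <- rep(0, n)
    } else {
      day_dir <- (wr$prevailing_dir + rnorm(1, 0, 55)) %% 360
      day_speed <- rgamma(1, shape = 4, scale = wr$mean_speed / 4)
      dir <- (day_dir + ar1_noise(n, 8)) %% 360
      speed <- pmax(0, day_speed * (1 + 0.15 * ar1_noise(n, 1)))
    }
    speed_max <- speed * (1.25 + pmax(0, rnorm(n, 0, 0.1)))

    temp_day <- 8 + 9 * sin(2 * pi * (doy - 110) / 365) + rnorm(1, 0, 3)
    temp <- temp_day + 3 * sin(2 * pi * ((seq_len(n) - 1) / 1440 - 0.375)) +
      0.2 * ar1_noise(n, 1)

    wet <- wr$type == "stochastic" && runif(1) < 0.4
    precip <- if (wet) {
      round(rbinom(n, 1, 0.06) * rgamma(n, shape = 0.8, scale = 0.15), 2)
    } else {
      rep(0, n)
    }

    cloudless <- if (wr$type == "stochastic") !wet && runif(1) < 0.25 else TRUE
    cloud_factor <- if (cloudless) 1 else runif(1, 0.2, 0.85)
    elev <- solar_elevation(ts, lat, lon)
    clear <- clear_sky_radiation(elev)
    radiation <- pmax(0, clear * cloud_factor * (1 + rnorm(n, 0, 0.01)))

    pressure <- 1013 + rnorm(1, 0, 8) + 0.3 * ar1_noise(n, 1)
    humidity <- pmin(100, pmax(30, 80 + rnorm(1, 0, 8) + 0.5 * ar1_noise(n, 1)))

    station <- tibble::tibble(
      timestamp = ts,
      temperature = temp,
      wind_speed = speed,
      wind_speed_max = speed_max,
      wind_direction = dir,
      precipitation = precip,
      global_radiation = radiation,
      air_pressure = pressure,
      humidity = humidity
    )

    ls_speed <- day_speed * (1 + rnorm(1, 0, 0.1) * (wr$type == "stochastic"))
    ls_dir <- (day_dir + rnorm(1, 0, 5) * (wr$type == "stochastic")) %% 360
    large_scale <- tibble::tibble(
      date = date,
      cell_lat = 54.5,
      cell_lon = 10,
      temperature = temp_day + rnorm(1, 0, 1),
      pressure = pressure[1] + rnorm(1, 0, 1),
      wind_u = -ls_speed * sin(ls_dir * pi / 180),
      wind_v = -ls_speed * cos(ls_dir * pi / 180)
    )

    day_info <- tibble::tibble(
      date = date, day_dir = day_dir, day_speed = day_speed,
      wet = wet, cloudless = cloudless, cloud_factor = cloud_factor
    )
    list(station = station, large_scale = large_scale, day_info = day_info)
  })
}

# Smooth AR(1) noise with unit marginal-ish scale times sd.
ar1_noise <- function(n, sd, phi = 0.97) {
  as.numeric(stats::filter(rnorm(n, 0, sd * sqrt(1 - phi^2)), phi,
                           method = "recursive"))
}

# Idealised clear-sky global radiation (W/m^2) from solar elevation (deg).
clear_sky_radiation <- function(elev_deg) {
  s <- sin(pmax(0, elev_deg) * pi / 180)
  1000 * s^1.15
}

# Wind at given instants, nearest-minute lookup in a station table.
# Returns a list with speed (m/s) and direction-from (deg).
wind_at <- function(station, times) {
  idx <- findInterval(as.numeric(times) + 30, as.numeric(station$timestamp))
  idx <- pmin(pmax(idx, 1L), nrow(station))
  list(speed = station$wind_speed[idx],
       direction = station$wind_direction[idx])
}

# Indexed form used in the flight-leg stepper: an O(1) minute-grid map from
# time to station row (station rows sit on a 1-min grid, possibly with date
# gaps, which are carried forward from the nearest earlier row).
wind_index <- function(station) {
  t <- as.numeric(station$timestamp)
  t0 <- t[1]
  pos <- (t - t0) %/% 60 + 1
  map <- integer(pos[length(pos)])
  map[pos] <- seq_along(pos)
  map <- cummax(map)
  map[map == 0L] <- 1L
  list(t0 = t0, map = map, len = length(map),
       speed = station$wind_speed, dir = station$wind_direction)
}

wind_lookup <- function(widx, time_num) {
  p <- (time_num + 30 - widx$t0) %/% 60 + 1
  p <- min(max(p, 1), widx$len)
  i <- widx$map[p]
  list(speed = widx$speed[i], direction = widx$dir[i])
}
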