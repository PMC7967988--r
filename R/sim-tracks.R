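#' Simulate GPS tracks with known ground truth
#'
#' Builds one track per individual-year in the roster: a wintering residency
#' (low-speed scatter within a few km of the shared wintering centroid), an
#' optional pre-departure relocation of less than 30 km, an evening departure
#' at the planted day-of-year, a first stop-over about a third of the way to
#' the breeding site (sometimes a second one further on), a breeding
#' residency of 47--62 days of non-directional scatter, a return leg with a
#' nearer stop-over, and a post-arrival wintering residency. Flight legs are
#' piecewise constant-velocity great-circle segments; the realised ground
#' speed of every airborne fix is `airspeed + twc_speed_gain * 3.6 * TWC`
#' with the tailwind component taken from the station wind at the nearest
#' minute, and flight altitude rises with headwind at
#' `altitude_headwind_slope` m per m/s. Gaussian positional jitter
#' (`jitter_m`) is added to every fix.
#'
#' The planted departure day is
#' `base_departure_doy + beta_distance * (distance - ref_distance_km) +
#' beta_latitude * (breeding_lat - ref_latitude) + intercept + noise`,
#' kept as a continuous latent day-of-year in the ground truth (so planted
#' slopes are recoverable exactly when the noise terms are zero); the
#' realised departure instant falls on `floor(latent)` during the configured
#' evening window. The true arrival is the instant the return leg first
#' comes within 30 km of the wintering centroid. A fraction `p_lost_return`
#' of tracks end at the breeding site (transmitter loss), giving
#' departure-only years.
#'
#' @param roster Tibble from [generate_roster()].
#' @param config A [sim_config()].
#' @param weather Optional pre-generated weather list from
#'   [simulate_weather()]; by default, station weather is generated for the
#'   dates the tracks need.
#' @return A list with `fixes` (tibble: `individual_id`, `timestamp`, `lat`,
#'   `lon`, `ground_speed` km/h, `altitude` m) and `truth` (one row per
#'   individual-year with the planted quantities).
#' @export
simulate_tracks <- function(roster, config, weather = NULL) {
  stopifnot(inherits(config, "sim_config"), nrow(roster) >= 1)
  ws <- config$wintering_site

  ind_years <- roster |>
    dplyr::mutate(year = purrr::map2(.data$first_year, .data$n_years,
                                     ~ seq(.x, .x + .y - 1))) |>
    tidyr::unnest("year") |>
    dplyr::select("individual_id", "sex", "breeding_lat", "breeding_lon",
                  "distance_km", "intercept_days", "year")

  itins <- purrr::pmap(ind_years, function(...) {
    row <- list(...)
    plan_itinerary(row, config)
  })

  if (is.null(weather)) {
    dates <- sort(unique(do.call(c, purrr::map(itins, "weather_dates"))))
    weather <- simulate_weather(config, dates = dates)
  }
  station <- weather$station

  widx <- wind_index(station)
  built <- purrr::map(itins, function(it) build_track(it, config, widx))

  fixes <- dplyr::bind_rows(purrr::map(built, "fixes")) |>
    dplyr::arrange(.data$individual_id, .data$timestamp)
  truth <- dplyr::bind_rows(purrr::map(built, "truth"))
  list(fixes = fixes, truth = truth)
}

# Itinerary: all planted times/places for one individual-year, no fix-level
# randomness yet. Evening departure on floor(latent) day.
plan_itinerary <- function(row, config) {
  ws <- config$wintering_site
  withr::with_seed(
    derive_seed(config$seed, paste0("itin", row$individual_id, row$year)), {
      latent <- config$base_departure_doy +
        config$beta_distance * (row$distance_km - config$ref_distance_km) +
        config$beta_latitude * (row$breeding_lat - config$ref_latitude) +
        row$intercept_days + rnorm(1, 0, config$sigma_noise)
      dep_day <- as.Date(paste0(row$year, "-01-01")) + floor(latent) - 1
      dep_hour <- runif(1, config$departure_window_utc[1],
                        config$departure_window_utc[2])
      dep_time <- as.POSIXct(paste0(format(dep_day), " 00:00:00"), tz = "UTC") +
        dep_hour * 3600

      reloc <- NULL
      if (runif(1) < config$p_relocation) {
        reloc <- list(
          dist = runif(1, 10, 28), bearing = runif(1, 0, 360),
          time = dep_time - runif(1, 1, 5) * 86400
        )
        p <- destination_point(ws[["lat"]], ws[["lon"]], reloc$bearing,
                               reloc$dist)
        reloc$lat <- p$lat; reloc$lon <- p$lon
      }

      total <- row$distance_km
      frac1 <- min(0.45, max(0.2, rnorm(1, config$first_stop_fraction, 0.05)))
      stop1 <- off_route_point(ws, row, frac1, 15)
      stop1_dur <- runif(1, 2, 10)
      stop2 <- NULL
      if (runif(1) < 0.5 && total > 1200) {
        stop2 <- off_route_point(ws, row, runif(1, 0.6, 0.8), 15)
        stop2$dur <- runif(1, 1, 6)
      }
      breeding_stay <- round(runif(1, config$breeding_stay_range[1],
                                   config$breeding_stay_range[2]))
      lost <- runif(1) < config$p_lost_return
      ret_stop <- off_route_point(ws, row, runif(1, 150, 600) / total, 15)
      ret_stop_dur <- runif(1, 2, 8)

      start_time <- dep_time - 30 * 86400
      # weather is only consumed while airborne; cover the outbound and
      # return flight windows (legs bounded by a 40 km/h worst case)
      dep_date <- as.Date(dep_time)
      stops_d <- stop1_dur + (stop2$dur %||% 0)
      outbound <- seq(dep_date - 1,
                      dep_date + ceiling(stops_d + total / 40 / 24) + 2,
                      by = "day")
      ret_lo <- dep_date + floor(stops_d + breeding_stay)
      ret_hi <- dep_date + ceiling(2 * total / 40 / 24 + stops_d +
                                     breeding_stay + ret_stop_dur) + 2
      weather_dates <- c(outbound, seq(ret_lo, ret_hi, by = "day"))
      list(row = row, latent_doy = latent, dep_time = dep_time, reloc = reloc,
           stop1 = stop1, stop1_dur = stop1_dur, stop2 = stop2,
           breeding_stay = breeding_stay, lost = lost, ret_stop = ret_stop,
           ret_stop_dur = ret_stop_dur, start_time = start_time,
           weather_dates = weather_dates)
    })
}

# A stop-over site: the great-circle point at `frac` of the route, displaced
# sideways by up to `off_km`.
off_route_point <- function(ws, row, frac, off_km) {
  br <- bearing_deg(ws[["lat"]], ws[["lon"]], row$breeding_lat, row$breeding_lon)
  p <- destination_point(ws[["lat"]], ws[["lon"]], br, frac * row$distance_km)
  p2 <- destination_point(p$lat, p$lon, runif(1, 0, 360), runif(1, 0, off_km))
  list(lat = p2$lat, lon = p2$lon)
}

# Fix-level construction of one individual-year track.
build_track <- function(it, config, widx) {
  row <- it$row
  ws <- config$wintering_site
  withr::with_seed(
    derive_seed(config$seed, paste0("fix", row$individual_id, row$year)), {
      segs <- list()
      add <- function(s) segs[[length(segs) + 1]] <<- s

      # wintering residency (and optional relocation site)
      if (is.null(it$reloc)) {
        add(residency_fixes(ws[["lat"]], ws[["lon"]], it$start_time,
                            it$dep_time, config, scatter_km = 1.5))
        cur <- list(lat = ws[["lat"]], lon = ws[["lon"]])
      } else {
        add(residency_fixes(ws[["lat"]], ws[["lon"]], it$start_time,
                            it$reloc$time, config, scatter_km = 1.5))
        leg <- flight_leg(ws[["lat"]], ws[["lon"]], it$reloc$lat, it$reloc$lon,
                          it$reloc$time, config, widx)
        add(leg$fixes)
        add(residency_fixes(it$reloc$lat, it$reloc$lon, leg$end_time,
                            it$dep_time, config, scatter_km = 1.0))
        cur <- list(lat = it$reloc$lat, lon = it$reloc$lon)
      }

      # outbound: departure bout, first stop, (second stop), breeding
      leg <- flight_leg(cur$lat, cur$lon, it$stop1$lat, it$stop1$lon,
                        it$dep_time, config, widx)
      add(leg$fixes)
      t <- leg$end_time + it$stop1_dur * 86400
      add(residency_fixes(it$stop1$lat, it$stop1$lon, leg$end_time, t,
                          config, scatter_km = 1.0))
      cur <- it$stop1
      if (!is.null(it$stop2)) {
        leg <- flight_leg(cur$lat, cur$lon, it$stop2$lat, it$stop2$lon, t,
                          config, widx)
        add(leg$fixes)
        t2 <- leg$end_time + it$stop2$dur * 86400
        add(residency_fixes(it$stop2$lat, it$stop2$lon, leg$end_time, t2,
                            config, scatter_km = 1.0))
        cur <- it$stop2; t <- t2
      }
      leg <- flight_leg(cur$lat, cur$lon, row$breeding_lat, row$breeding_lon,
                        t, config, widx)
      add(leg$fixes)
      breed_end <- leg$end_time + it$breeding_stay * 86400
      add(residency_fixes(row$breeding_lat, row$breeding_lon, leg$end_time,
                          breed_end, config, scatter_km = 2.0))

      true_arrival <- NA_real_
      if (!it$lost) {
        # return: breeding -> return stop -> wintering
        leg <- flight_leg(row$breeding_lat, row$breeding_lon,
                          it$ret_stop$lat, it$ret_stop$lon, breed_end,
                          config, widx)
        add(leg$fixes)
        t <- leg$end_time + it$ret_stop_dur * 86400
        add(residency_fixes(it$ret_stop$lat, it$ret_stop$lon, leg$end_time, t,
                            config, scatter_km = 1.0))
        leg <- flight_leg(it$ret_stop$lat, it$ret_stop$lon,
                          ws[["lat"]], ws[["lon"]], t, config, widx,
                          arrival_radius_km = 30)
        add(leg$fixes)
        arr_time <- leg$crossing_time %||% leg$end_time
        true_arrival <- doy_frac(arr_time)
        add(residency_fixes(ws[["lat"]], ws[["lon"]], leg$end_time,
                            leg$end_time + 14 * 86400, config,
                            scatter_km = 1.5))
      }

      fixes <- dplyr::bind_rows(segs)
      # positional jitter, applied to every fix
      km_per_deg <- 111.19
      fixes$lat <- fixes$lat + rnorm(nrow(fixes), 0, config$jitter_m / 1000) /
        km_per_deg
      fixes$lon <- fixes$lon + rnorm(nrow(fixes), 0, config$jitter_m / 1000) /
        (km_per_deg * cos(fixes$lat * pi / 180))
      fixes$individual_id <- row$individual_id
      fixes <- fixes[, c("individual_id", "timestamp", "lat", "lon",
                         "ground_speed", "altitude")]

      truth <- tibble::tibble(
        individual_id = row$individual_id,
        year = row$year,
        sex = row$sex,
        true_departure_doy = it$latent_doy,
        departure_time = it$dep_time,
        true_arrival_doy = true_arrival,
        breeding_lat = row$breeding_lat,
        breeding_lon = row$breeding_lon,
        distance_km = row$distance_km,
        breeding_stay = it$breeding_stay,
        intercept_days = row$intercept_days,
        first_stop_lat = it$stop1$lat,
        first_stop_lon = it$stop1$lon,
        relocated = !is.null(it$reloc)
      )
      list(fixes = fixes, truth = truth)
    })
}

doy_frac <- function(time) {
  d <- as.Date(time, tz = "UTC")
  as.integer(strftime(d, "%j", tz = "UTC")) +
    (as.numeric(time) - as.numeric(as.POSIXct(paste0(format(d), " 00:00:00"),
                                              tz = "UTC"))) / 86400
}

residency_fixes <- function(lat, lon, from, to, config, scatter_km,
                            interval_min = config$residency_interval) {
  if (to <= from) {
    return(tibble::tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                          lat = numeric(), lon = numeric(),
                          ground_speed = numeric(), altitude = numeric()))
  }
  ts <- seq(from, to, by = interval_min * 60)
  ts <- ts[as.numeric(ts) < as.numeric(to) - 1e-9]  # next segment owns `to`
  n <- length(ts)
  km_per_deg <- 111.19
  tibble::tibble(
    timestamp = ts,
    lat = lat + rnorm(n, 0, scatter_km) / km_per_deg,
    lon = lon + rnorm(n, 0, scatter_km) / (km_per_deg * cos(lat * pi / 180)),
    ground_speed = runif(n, 0, 5),
    altitude = runif(n, 0, 30)
  )
}

# One great-circle flight leg with wind-dependent speed and altitude.
# If arrival_radius_km is given, records the continuous instant at which the
# leg first comes within that radius of the target (`crossing_time`).
flight_leg <- function(lat1, lon1, lat2, lon2, start_time, config, widx,
                       arrival_radius_km = NULL) {
  dt_min <- config$fix_interval
  airspeed <- max(45, rnorm(1, config$airspeed_mean, config$airspeed_sd))
  cur_lat <- lat1; cur_lon <- lon1
  t <- start_time
  rows <- list()
  crossing_time <- NULL
  remaining <- great_circle_km(cur_lat, cur_lon, lat2, lon2)
  i <- 0L
  while (remaining > 0.5 && i < 5000L) {
    i <- i + 1L
    heading <- bearing_deg(cur_lat, cur_lon, lat2, lon2)
    w <- wind_lookup(widx, as.numeric(t))
    twc <- if (w$speed > 0) {
      tailwind_component(w$speed, w$direction, heading)
    } else 0
    speed <- max(20, airspeed + config$twc_speed_gain * 3.6 * twc)
    alt <- max(10, config$altitude_base +
                 config$altitude_headwind_slope * (-twc) + rnorm(1, 0, 30))
    rows[[i]] <- c(as.numeric(t), cur_lat, cur_lon,
                   speed + rnorm(1, 0, 0.5), alt)
    step <- speed * dt_min / 60
    if (!is.null(arrival_radius_km) && is.null(crossing_time)) {
      if (remaining <= arrival_radius_km) {
        crossing_time <- t
      } else if (remaining - step <= arrival_radius_km) {
        # continuous instant of crossing the radius within this step
        crossing_time <- t + 3600 * (remaining - arrival_radius_km) / speed
      }
    }
    if (step >= remaining) {
      end_time <- t + 3600 * remaining / speed
      cur_lat <- lat2; cur_lon <- lon2
      remaining <- 0
      t <- end_time
      break
    }
    p <- destination_point(cur_lat, cur_lon, heading, step)
    cur_lat <- p$lat; cur_lon <- p$lon
    remaining <- remaining - step
    t <- t + dt_min * 60
  }
  m <- do.call(rbind, rows)
  fixes <- tibble::tibble(
    timestamp = as.POSIXct(m[, 1], tz = "UTC", origin = "1970-01-01"),
    lat = m[, 2], lon = m[, 3], ground_speed = m[, 4], altitude = m[, 5]
  )
  list(fixes = fixes, end_time = t, crossing_time = crossing_time)
}
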