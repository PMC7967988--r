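# Deterministic hand-built track fixtures (no RNG): residencies and
# constant-speed great-circle legs assembled into fix tibbles.

t_base <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")

make_residency <- function(lat, lon, from_h, to_h, step_min = 15,
                           speed = 2, wobble_km = 0.5) {
  ts <- seq(t_base + from_h * 3600, t_base + to_h * 3600, by = step_min * 60)
  n <- length(ts)
  # deterministic small scatter so clusters are non-directional
  ang <- seq_len(n) * 2.399963  # golden-angle spiral, no RNG
  tibble::tibble(
    timestamp = ts,
    lat = lat + wobble_km * cos(ang) / 111.19,
    lon = lon + wobble_km * sin(ang) / (111.19 * cos(lat * pi / 180)),
    ground_speed = rep(speed, n),
    altitude = rep(5, n)
  )
}

make_leg <- function(lat1, lon1, lat2, lon2, start_h, speed_kmh = 60,
                     step_min = 5) {
  start <- t_base + start_h * 3600
  total <- great_circle_km(lat1, lon1, lat2, lon2)
  step <- speed_kmh * step_min / 60
  rows <- list(c(as.numeric(start), lat1, lon1))
  cur <- c(lat1, lon1)
  t <- start
  remaining <- total
  while (remaining > step) {
    br <- bearing_deg(cur[1], cur[2], lat2, lon2)
    p <- migratimer:::destination_point(cur[1], cur[2], br, step)
    cur <- c(p$lat, p$lon)
    t <- t + step_min * 60
    remaining <- remaining - step
    rows[[length(rows) + 1]] <- c(as.numeric(t), cur[1], cur[2])
  }
  t <- t + 3600 * remaining / speed_kmh
  rows[[length(rows) + 1]] <- c(as.numeric(t), lat2, lon2)
  m <- do.call(rbind, rows)
  tibble::tibble(
    timestamp = as.POSIXct(m[, 1], tz = "UTC", origin = "1970-01-01"),
    lat = m[, 2], lon = m[, 3],
    ground_speed = rep(speed_kmh, nrow(m)),
    altitude = rep(800, nrow(m))
  )
}

bind_track <- function(..., id = "B01") {
  out <- dplyr::bind_rows(...)
  out$individual_id <- id
  out[!duplicated(out$timestamp), ]
}

winter_centroid <- c(lat = 54.0, lon = 8.85)

# a standard migratory fixture: 2 d wintering, departure at +48 h to a stop
# 500 km NE, 3 d stop, leg to breeding 1600 km NE, long stay, return
standard_track <- function(breeding_stay_h = 24 * 30, id = "B01") {
  stop1 <- migratimer:::destination_point(54, 8.85, 45, 500)
  breed <- migratimer:::destination_point(54, 8.85, 45, 1600)
  w <- make_residency(54, 8.85, 0, 48)
  leg1 <- make_leg(54, 8.85, stop1$lat, stop1$lon, 48, 70)
  s1_end <- 48 + great_circle_km(54, 8.85, stop1$lat, stop1$lon) / 70 + 72
  s1 <- make_residency(stop1$lat, stop1$lon,
                       48 + great_circle_km(54, 8.85, stop1$lat, stop1$lon) / 70,
                       s1_end)
  leg2 <- make_leg(stop1$lat, stop1$lon, breed$lat, breed$lon, s1_end, 70)
  b_start <- s1_end + great_circle_km(stop1$lat, stop1$lon,
                                      breed$lat, breed$lon) / 70
  b <- make_residency(breed$lat, breed$lon, b_start, b_start + breeding_stay_h)
  list(fixes = bind_track(w, leg1, s1, leg2, b, id = id),
       stop1 = stop1, breeding = breed,
       departure_time = t_base + 48 * 3600)
}
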