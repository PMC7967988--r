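test_that("the breeding residency is classified at the planted site", {
  trk <- standard_track()
  s <- classify_sites(trk$fixes, winter_centroid)
  expect_equal(sum(s$kind == "breeding"), 1)
  b <- s[s$kind == "breeding", ]
  expect_lt(great_circle_km(b$lat, b$lon, trk$breeding$lat,
                            trk$breeding$lon), 50)
  expect_true(any(s$kind == "stopover"))
  expect_true(any(s$kind == "wintering"))
  # breeding stay dominates every stop-over duration
  expect_true(b$duration_d >= max(s$duration_d[s$kind == "stopover"]))
})

test_that("distance dominates among clusters qualifying as breeding", {
  near <- migratimer:::destination_point(54, 8.85, 45, 1000)
  far <- migratimer:::destination_point(54, 8.85, 45, 1500)
  w <- make_residency(54, 8.85, 0, 48)
  l1 <- make_leg(54, 8.85, near$lat, near$lon, 48, 70)
  rnear <- make_residency(near$lat, near$lon, 48 + 15, 48 + 15 + 60 * 24)
  l2 <- make_leg(near$lat, near$lon, far$lat, far$lon, 48 + 16 + 60 * 24, 70)
  rfar <- make_residency(far$lat, far$lon, 48 + 24 + 60 * 24,
                         48 + 24 + 110 * 24)
  fx <- bind_track(w, l1, rnear, l2, rfar)
  s <- classify_sites(fx, winter_centroid)
  b <- s[s$kind == "breeding", ]
  expect_equal(nrow(b), 1)
  expect_lt(great_circle_km(b$lat, b$lon, far$lat, far$lon), 50)
})

test_that("a short stay at maximum distance leaves breeding unresolved", {
  trk <- standard_track(breeding_stay_h = 24 * 10)  # 10 d < 21-d gate
  expect_message(s <- classify_sites(trk$fixes, winter_centroid),
                 "unresolved")
  expect_equal(sum(s$kind == "breeding"), 0)
  expect_true(isTRUE(attr(s, "breeding_unresolved")))
})

test_that("first stop skips sub-30-km relocations and obeys the triangle", {
  trk <- standard_track()
  dep <- detect_departure(trk$fixes, winter_centroid)
  s <- classify_sites(trk$fixes, winter_centroid)
  fs <- first_stop(trk$fixes, dep, s, winter_centroid)
  expect_equal(fs$kind, "stopover")
  expect_equal(fs$linear_km, 500, tolerance = 0.05)
  expect_gte(fs$flown_km, fs$linear_km)
  expect_equal(fs$flight_time_h, 500 / 70, tolerance = 0.3)
})

test_that("nonstop migration makes the breeding site the first stop", {
  breed <- migratimer:::destination_point(54, 8.85, 45, 1600)
  w <- make_residency(54, 8.85, 0, 48)
  leg <- make_leg(54, 8.85, breed$lat, breed$lon, 48, 70)
  b <- make_residency(breed$lat, breed$lon, 48 + 1600 / 70 + 0.5,
                      48 + 1600 / 70 + 24 * 40)
  fx <- bind_track(w, leg, b)
  dep <- detect_departure(fx, winter_centroid)
  s <- classify_sites(fx, winter_centroid)
  fs <- first_stop(fx, dep, s, winter_centroid)
  expect_equal(fs$kind, "breeding")
  expect_equal(fs$linear_km, 1600, tolerance = 0.05)
})

test_that("curvature is zero on straight bouts and exact on a dogleg", {
  straight <- make_leg(54, 8.85, 58, 20, 0, 70)
  expect_lt(abs(curvature_pct(straight)), 0.2)
  # two equal 100-km legs at a right angle near the equator: flown 200,
  # linear ~141.42, curvature ~29.3%
  mid <- migratimer:::destination_point(0, 0, 90, 100)
  l1 <- make_leg(0, 0, mid$lat, mid$lon, 0, 60)
  endp <- migratimer:::destination_point(mid$lat, mid$lon, 0, 100)
  l2 <- make_leg(mid$lat, mid$lon, endp$lat, endp$lon, 100 / 60 + 1 / 60, 60)
  dog <- bind_track(l1, l2)
  expect_equal(curvature_pct(dog), 100 * (200 - sqrt(2) * 100) / 200,
               tolerance = 0.1)
})

test_that("bouts with over-5-min gaps are not evaluable for curvature", {
  leg <- make_leg(54, 8.85, 58, 20, 0, 70)
  gap <- leg[-(10:11), ]  # creates a 15-min hole
  expect_true(is.na(curvature_pct(gap)))
})

test_that("corridor statistics average in-box flight correctly", {
  east <- make_leg(54, 8.0, 54, 11.9, 0, 60)
  east$ground_speed <- rep(c(60, 80), length.out = nrow(east))
  box <- c(53.4, 55.5, 8.2, 11.5)
  cs <- corridor_stats(east, box)
  expect_equal(cs$mean_direction, 90, tolerance = 2)
  expect_equal(cs$mean_speed, 70, tolerance = 1)
  # circular mean of bearings straddling north
  two <- tibble::tibble(
    timestamp = t_base + c(0, 60, 120),
    lat = c(54, 54.05, 54.1),
    lon = c(10, 10 - 0.015, 10),
    ground_speed = 60, altitude = 500
  )
  cs2 <- corridor_stats(two, box)
  expect_lt(circular_diff_deg(cs2$mean_direction, 0), 12)
  # fewer than 2 in-box fixes is not evaluable
  expect_true(is.na(corridor_stats(east[1, ], box)$mean_direction))
})

test_that("breeding centroids are recovered within 50 km on simulated data", {
  cfg <- sim_config(n_individuals = 6, years = 2017, seed = 23)
  trk <- simulate_tracks(generate_roster(cfg), cfg)
  hits <- vapply(seq_len(nrow(trk$truth)), function(i) {
    tt <- trk$truth[i, ]
    fx <- trk$fixes[trk$fixes$individual_id == tt$individual_id, ]
    s <- classify_sites(fx, cfg$wintering_site)
    b <- s[s$kind == "breeding", ]
    nrow(b) == 1 &&
      great_circle_km(b$lat, b$lon, tt$breeding_lat, tt$breeding_lon) < 50
  }, logical(1))
  expect_true(all(hits))
})
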