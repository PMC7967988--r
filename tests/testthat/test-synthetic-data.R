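test_that("roster mirrors the configured population", {
  cfg <- sim_config(n_individuals = 23, seed = 5)
  r <- generate_roster(cfg)
  expect_equal(nrow(r), 23)
  expect_equal(sum(r$sex == "F"), 11)
  expect_equal(sum(r$sex == "M"), 12)
  expect_true(all(r$breeding_lat >= 55 & r$breeding_lat <= 70))
  expect_true(all(r$breeding_lon >= 20 & r$breeding_lon <= 65))
  # degenerate SD pins every intercept at zero
  r0 <- generate_roster(sim_config(n_individuals = 4, sigma_individual = 0))
  expect_equal(r0$intercept_days, rep(0, 4))
  # determinism
  expect_identical(generate_roster(cfg), generate_roster(cfg))
})

test_that("invalid configuration ranges are refused", {
  expect_error(sim_config(breeding_lat_range = c(70, 55)), "min must not")
  expect_error(sim_config(fix_interval = 0), "fix_interval")
  expect_error(sim_config(fix_interval = 20), "fix_interval")
  expect_error(sim_config(n_individuals = 0), "n_individuals")
  expect_error(sim_config(sigma_noise = -1), "non-negative")
})

test_that("identical configurations give identical tracks and weather", {
  cfg <- sim_config(n_individuals = 2, years = 2017, seed = 99)
  r <- generate_roster(cfg)
  a <- simulate_tracks(r, cfg)
  b <- simulate_tracks(r, cfg)
  expect_identical(a$fixes, b$fixes)
  expect_identical(a$truth, b$truth)
  wa <- simulate_weather(cfg, dates = as.Date("2017-04-10") + 0:1)
  wb <- simulate_weather(cfg, dates = as.Date("2017-04-10") + 0:1)
  expect_identical(wa$station, wb$station)
  # per-date seeding: a day simulated alone equals the same day in a span
  w1 <- simulate_weather(cfg, dates = as.Date("2017-04-11"))
  expect_identical(w1$station,
                   wb$station[as.Date(wb$station$timestamp) ==
                                as.Date("2017-04-11"), ])
})

test_that("planted timing slopes are recoverable to machine precision", {
  cfg <- sim_config(n_individuals = 12, years = 2017, seed = 21,
                    sigma_individual = 0, sigma_noise = 0)
  r <- generate_roster(cfg)
  trk <- simulate_tracks(r, cfg)
  fit <- lm(true_departure_doy ~ distance_km + breeding_lat, data = trk$truth)
  expect_equal(unname(coef(fit)["distance_km"]), cfg$beta_distance,
               tolerance = 1e-10)
  expect_equal(unname(coef(fit)["breeding_lat"]), cfg$beta_latitude,
               tolerance = 1e-10)
})

test_that("a farther-breeding bird departs later before noise", {
  cfg <- sim_config(seed = 1, sigma_individual = 0, sigma_noise = 0)
  r <- generate_roster(sim_config(n_individuals = 2, seed = 1,
                                  sigma_individual = 0, sigma_noise = 0))
  r$breeding_lat <- c(60, 60)
  r$breeding_lon <- c(30, 60)
  ws <- cfg$wintering_site
  r$distance_km <- great_circle_km(ws["lat"], ws["lon"],
                                   r$breeding_lat, r$breeding_lon)
  r$intercept_days <- 0
  r$first_year <- 2017L; r$n_years <- 1
  trk <- simulate_tracks(r, sim_config(n_individuals = 2, seed = 1,
                                       sigma_individual = 0, sigma_noise = 0))
  truth <- trk$truth[order(trk$truth$individual_id), ]
  expect_gt(truth$true_departure_doy[2], truth$true_departure_doy[1])
})

test_that("calm wind gives departure-bout ground speeds at the airspeed", {
  cfg <- sim_config(n_individuals = 1, years = 2017, seed = 8,
                    wind_regime = list(type = "calm"),
                    airspeed_mean = 60, airspeed_sd = 0, p_relocation = 0)
  trk <- simulate_tracks(generate_roster(cfg), cfg)
  dep <- trk$truth$departure_time[1]
  bout <- trk$fixes[trk$fixes$timestamp >= dep &
                      trk$fixes$timestamp <= dep + 4 * 3600 &
                      trk$fixes$ground_speed > 20, ]
  expect_gt(nrow(bout), 20)
  expect_true(all(abs(bout$ground_speed - 60) < 3))
})

test_that("station weather honours a constant regime and dry-day zeros", {
  cfg <- sim_config(seed = 2, wind_regime = list(type = "constant",
                                                 dir = 225, speed = 8))
  wx <- simulate_weather(cfg, dates = as.Date("2017-04-15"))
  expect_equal(nrow(wx$station), 1440)
  expect_true(all(wx$station$wind_direction == 225))
  expect_true(all(wx$station$wind_speed == 8))
  expect_true(all(wx$station$precipitation == 0))
  # zero-precipitation reference day forces the difference fallback
  sun <- sunrise_sunset(as.Date("2017-04-15"), 54.132, 8.877)
  p <- daylight_mean(wx$station, sun, "precipitation")
  ct <- contrast_value(0.4, p)
  expect_true(ct$fallback_used)
  expect_equal(ct$value, 0.4)
  # stochastic regime produces dry days with exact zeros among wet ones
  cfg2 <- sim_config(seed = 3)
  wx2 <- simulate_weather(cfg2, dates = as.Date("2017-04-01") + 0:9)
  daily <- tapply(wx2$station$precipitation,
                  as.Date(wx2$station$timestamp), sum)
  expect_true(any(daily == 0) && any(daily > 0))
})

test_that("large-scale wind components follow the meteorological convention", {
  cfg <- sim_config(seed = 2, wind_regime = list(type = "constant",
                                                 dir = 270, speed = 10))
  wx <- simulate_weather(cfg, dates = as.Date("2017-04-15"))
  # wind FROM west (270): air moves eastward -> u = +10, v = 0
  expect_equal(wx$large_scale$wind_u, 10, tolerance = 1e-8)
  expect_equal(wx$large_scale$wind_v, 0, tolerance = 1e-8)
})

test_that("tracks have bounded gaps, one departure and at most one arrival", {
  cfg <- sim_config(n_individuals = 3, years = 2016:2017, seed = 31)
  trk <- simulate_tracks(generate_roster(cfg), cfg)
  gaps <- trk$fixes |>
    dplyr::group_by(individual_id,
                    yr = format(timestamp, "%Y")) |>
    dplyr::summarise(g = max(diff(as.numeric(timestamp))) / 60,
                     .groups = "drop")
  expect_true(all(gaps$g <= cfg$residency_interval + 1e-9))
  expect_true(all(trk$truth$breeding_stay >= 47 &
                    trk$truth$breeding_stay <= 62))
  # exactly one planted departure per individual-year, arrivals at most one
  expect_equal(anyDuplicated(trk$truth[, c("individual_id", "year")]), 0L)
})

test_that("simulated fixes round-trip through the Movebank CSV format", {
  cfg <- sim_config(n_individuals = 1, years = 2017, seed = 12)
  trk <- simulate_tracks(generate_roster(cfg), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixes(trk$fixes, path)
  back <- read_fixes(path)
  expect_equal(nrow(back), nrow(trk$fixes))
  expect_equal(back$lat, trk$fixes$lat, tolerance = 1e-9)
  expect_equal(back$ground_speed, trk$fixes$ground_speed, tolerance = 1e-9)
  expect_true(all(abs(as.numeric(back$timestamp) -
                        as.numeric(trk$fixes$timestamp)) < 0.01))
})
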