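test_that("tailwind component reproduces the analytic cases", {
  expect_equal(tailwind_component(10, 225, 45), 10)    # pure tailwind
  expect_equal(tailwind_component(10, 135, 45), 0,     # crosswind
               tolerance = 1e-12)
  expect_equal(tailwind_component(10, 45, 45), -10)    # pure headwind
  expect_error(tailwind_component(-1, 0, 0), "non-negative")
})

test_that("tailwind component is bounded by wind speed and angle-periodic", {
  set.seed(11)
  v <- runif(5000, 0, 30)
  wd <- runif(5000, -720, 720)
  fd <- runif(5000, -720, 720)
  twc <- tailwind_component(v, wd, fd)
  expect_true(all(abs(twc) <= v + 1e-12))
  expect_equal(twc, tailwind_component(v, wd + 360, fd - 360),
               tolerance = 1e-10)
})

test_that("daylight means are arithmetic except for circular wind direction", {
  ts <- as.POSIXct("2017-04-15 10:00:00", tz = "UTC") + 60 * (0:9)
  rec <- tibble::tibble(
    timestamp = ts,
    temperature = rep(12, 10),
    wind_direction = rep(c(350, 10), 5)
  )
  win <- list(ts[1], ts[10])
  expect_equal(daylight_mean(rec, win, "temperature"), 12)
  expect_equal(daylight_mean(rec, win, "wind_direction"), 0)
  rec$wind_direction <- rep(c(0, 180), 5)  # zero resultant
  expect_true(is.na(daylight_mean(rec, win, "wind_direction")))
  expect_true(is.na(daylight_mean(rec, list(ts[1] - 7200, ts[1] - 3600),
                                  "temperature")))
})

test_that("contrasts are quotients with a difference fallback at zero", {
  expect_equal(contrast_value(5, 4)$value, 1.25)
  expect_false(contrast_value(5, 4)$fallback_used)
  z <- contrast_value(5, 0)
  expect_equal(z$value, 5)
  expect_true(z$fallback_used)
  expect_equal(contrast_value(3.7, 3.7)$value, 1)
  expect_true(is.na(contrast_value(NA, 2)$value))
})

test_that("the cloudiness proxy scores clear and overcast days correctly", {
  cfg <- sim_config(seed = 6, wind_regime = list(type = "constant",
                                                 dir = 225, speed = 5))
  days <- as.Date("2017-04-10") + 0:5
  wx <- simulate_weather(cfg, dates = days)
  st <- wx$station
  # constant regime days are all cloudless; synthesise one overcast day at
  # 30% of the clear-sky curve
  overcast <- st[as.Date(st$timestamp) == days[6], ]
  overcast$timestamp <- overcast$timestamp + 6 * 86400
  overcast$global_radiation <- overcast$global_radiation * 0.3
  score <- cloudiness_proxy(dplyr::bind_rows(st, overcast),
                            cloudless_days = days[1:5],
                            score_days = c(days[1], days[6] + 6))
  sun <- sunrise_sunset(days[1], 54.132, 8.877)
  clear_mean <- daylight_mean(st, sun, "global_radiation")
  expect_lt(abs(score$cloudiness[1]), 0.05 * clear_mean)
  expect_equal(score$cloudiness[2], 0.7 * clear_mean, tolerance = 0.08)
  expect_error(cloudiness_proxy(st, cloudless_days = days[1:4]),
               "at least 5")
})

test_that("build_contrasts yields 24 weather and 2 TWC contrasts", {
  cfg <- sim_config(seed = 4)
  ev <- tibble::tibble(individual_id = "C01", year = 2017, kind = "departure",
                       day_of_year = 108L, time_of_day = "19:30",
                       mean_direction = 45,
                       timestamp = as.POSIXct("2017-04-18 19:30:00",
                                              tz = "UTC"))
  d <- as.Date("2017-04-18")
  wx <- simulate_weather(cfg, dates = c(d - 1, d,
                                        as.Date(paste0(2013:2016, "-04-18"))))
  ct <- build_contrasts(ev, wx$station, wx$large_scale)
  expect_equal(nrow(ct), 26)
  expect_equal(sum(ct$variable != "twc"), 24)
  expect_equal(sort(unique(ct$condition)),
               sort(c("prev_day_local", "four_year_local",
                      "prev_day_large", "four_year_large")))
  ct24 <- build_contrasts(ev, wx$station, wx$large_scale, include_twc = FALSE)
  expect_equal(nrow(ct24), 24)
})

test_that("self-referencing weather gives unit quotients and zero fallbacks", {
  ts_day <- function(d) as.POSIXct(paste(d, "00:00:00"), tz = "UTC") +
    60 * (0:1439)
  days <- c(as.Date("2017-04-17"), as.Date("2017-04-18"),
            as.Date(paste0(2013:2016, "-04-18")))
  st <- dplyr::bind_rows(lapply(days, function(d) tibble::tibble(
    timestamp = ts_day(d), temperature = 10, wind_speed = 5,
    wind_speed_max = 7, wind_direction = 225, precipitation = 0,
    global_radiation = 300, air_pressure = 1013, humidity = 80)))
  lg <- tibble::tibble(date = days, cell_lat = 54.5, cell_lon = 10,
                       temperature = 10, pressure = 1013,
                       wind_u = 3.5, wind_v = 3.5)
  ev <- tibble::tibble(individual_id = "C01", year = 2017, kind = "departure",
                       day_of_year = 108L, time_of_day = "19:30",
                       mean_direction = 45,
                       timestamp = as.POSIXct("2017-04-18 19:30:00",
                                              tz = "UTC"))
  ct <- build_contrasts(ev, st, lg)
  quot <- ct[!ct$fallback_used, ]
  expect_true(all(abs(quot$value - 1) < 1e-8))
  fb <- ct[ct$fallback_used, ]                   # precipitation: 0 vs 0
  expect_true(all(fb$variable == "precipitation"))
  expect_true(all(fb$value == 0))
})

test_that("missing reference windows propagate as missing contrasts", {
  cfg <- sim_config(seed = 4)
  ev <- tibble::tibble(individual_id = "C01", year = 2017, kind = "departure",
                       day_of_year = 108L, time_of_day = "19:30",
                       mean_direction = 45,
                       timestamp = as.POSIXct("2017-04-18 19:30:00",
                                              tz = "UTC"))
  d <- as.Date("2017-04-18")
  wx <- simulate_weather(cfg, dates = c(d - 1, d))  # no 4-year reference
  ct <- build_contrasts(ev, wx$station, wx$large_scale)
  expect_true(all(is.na(ct$value[grepl("four_year", ct$condition)])))
  expect_true(all(!is.na(ct$value[ct$condition == "prev_day_local"])))
})
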