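#' Tailwind component of wind support
#'
#' `TWC = v * cos(x)`, where `v` is the wind speed (m/s) and `x` is the
#' angular deviation between the tailwind direction (the direction opposite
#' to the bird's flight direction) and the meteorological wind direction
#' (degrees FROM). Positive values are wind assistance along the track,
#' negative values headwind; `|TWC| <= v` always.
#'
#' @param wind_speed Wind speed in m/s (non-negative), vectorised.
#' @param wind_direction_from Direction the wind blows from, degrees.
#' @param flight_direction Direction of travel, degrees.
#' @return Tailwind component in m/s.
#' @examples
#' tailwind_component(10, 225, 45)  # pure tailwind: +10
#' tailwind_component(10, 135, 45)  # crosswind: 0
#' tailwind_component(10, 45, 45)   # pure headwind: -10
#' @export
tailwind_component <- function(wind_speed, wind_direction_from,
                               flight_direction) {
  if (any(wind_speed < 0)) stop("wind_speed must be non-negative", call. = FALSE)
  x <- circular_diff_deg((flight_direction + 180) %% 360,
                         wind_direction_from %% 360)
  wind_speed * cos(x * pi / 180)
}

#' Daylight-window mean of a station variable
#'
#' Arithmetic mean of the 1-min records between sunrise and sunset, except
#' for `wind_direction` which is averaged as the direction of the circular
#' resultant vector. An empty window, or a wind-direction set with zero
#' resultant length, is "not evaluable" and yields `NA`.
#'
#' @param records Station tibble (see [read_station_weather()] columns).
#' @param window List with POSIXct `sunrise` and `sunset` (e.g. from
#'   [sunrise_sunset()]), or any two-element list of POSIXct bounds.
#' @param variable Column name to average.
#' @return A single numeric value, or `NA` if not evaluable.
#' @export
daylight_mean <- function(records, window, variable) {
  stopifnot(variable %in% names(records))
  lo <- window[[1]]; hi <- window[[2]]
  x <- records[[variable]][records$timestamp >= lo & records$timestamp <= hi]
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  if (variable == "wind_direction") circular_mean_deg(x) else mean(x)
}

#' Cloudiness proxy from global radiation
#'
#' Fits a smooth clear-sky curve of global radiation against time of day
#' (a penalized cubic regression spline, smoothness chosen by GCV) on at
#' least five pooled cloudless days, then scores any day by the mean
#' deviation of the fitted clear-sky value from the observed radiation over
#' the daylight window. Scores near zero mean cloudless; larger positive
#' scores mean heavier attenuation.
#'
#' @param records Station tibble with `timestamp` and `global_radiation`.
#' @param cloudless_days At least five `Date`s with full daylight coverage,
#'   used to train the clear-sky curve.
#' @param score_days Dates to score (default: every date present).
#' @param lat,lon Station location, used to bound the daylight window.
#' @return A tibble with `date` and `cloudiness` (W/m^2 mean deviation).
#' @export
cloudiness_proxy <- function(records, cloudless_days, score_days = NULL,
                             lat = 54.132, lon = 8.877) {
  cloudless_days <- as.Date(cloudless_days)
  if (length(cloudless_days) < 5) {
    stop("at least 5 cloudless training days are required", call. = FALSE)
  }
  rec_date <- as.Date(records$timestamp, tz = "UTC")
  min_of_day <- (as.numeric(records$timestamp) %% 86400) / 60

  train <- rec_date %in% cloudless_days
  if (!any(train)) stop("no records on the given cloudless days", call. = FALSE)
  fit <- mgcv::gam(rad ~ s(tod, bs = "cs", k = 20),
                   data = data.frame(rad = records$global_radiation[train],
                                     tod = min_of_day[train]))

  if (is.null(score_days)) score_days <- sort(unique(rec_date))
  score_days <- as.Date(score_days)
  score <- purrr::map_dbl(score_days, function(d) {
    sun <- sunrise_sunset(d, lat, lon)
    in_day <- rec_date == d & records$timestamp >= sun$sunrise &
      records$timestamp <= sun$sunset
    if (!any(in_day)) return(NA_real_)
    pred <- predict(fit, newdata = data.frame(tod = min_of_day[in_day]))
    mean(pred - records$global_radiation[in_day])
  })
  tibble::tibble(date = score_days, cloudiness = score)
}

#' Contrast a departure/arrival-day value against a reference
#'
#' The event-day mean is divided by the reference mean; when the reference is
#' exactly zero (as precipitation means are on dry days) the difference is
#' used instead and flagged. Missing inputs propagate as missing.
#'
#' @param day_value Event-day aggregated value.
#' @param reference_value Reference-window aggregated value.
#' @return A list with `value` and `fallback_used`.
#' @export
contrast_value <- function(day_value, reference_value) {
  if (is.na(day_value) || is.na(reference_value)) {
    return(list(value = NA_real_, fallback_used = NA))
  }
  if (reference_value == 0) {
    list(value = day_value - reference_value, fallback_used = TRUE)
  } else {
    list(value = day_value / reference_value, fallback_used = FALSE)
  }
}

local_weather_vars <- function() {
  c("temperature", "wind_speed", "wind_speed_max", "wind_direction",
    "precipitation", "global_radiation", "air_pressure", "humidity")
}

large_weather_vars <- function() {
  c("temperature", "pressure", "wind_u", "wind_v")
}

#' Build the 24 weather contrasts (and 2 TWC contrasts) for one event
#'
#' For a departure or arrival event, computes the event-day weather aggregated
#' over the daylight window (local station variables; circular mean for wind
#' direction) and over 24 h (large-scale variables), and contrasts it against
#' two references: the previous day, and the mean over the same calendar date
#' in the four preceding years. That yields 8 local x 2 + 4 large-scale x 2 =
#' 24 contrasts; optionally two further contrasts of the event-day tailwind
#' component against the same two references computed from station wind.
#' 29 February references map to 28 February in non-leap years. A reference
#' window without data marks the contrast missing (`NA`), never zero.
#'
#' @param event One-row events tibble (see [detect_departure()]), needing at
#'   least `timestamp` (or `year` + `day_of_year`) and, for the TWC
#'   contrasts, `mean_direction`.
#' @param station Local station tibble covering the event day, the previous
#'   day and the four same-date previous years.
#' @param large_scale Daily large-scale tibble covering the same windows.
#' @param lat,lon Station location for the daylight window.
#' @param include_twc Also compute the two TWC contrasts (requires a finite
#'   `mean_direction` on the event).
#' @return A tibble with `variable`, `condition` (`prev_day_local`,
#'   `four_year_local`, `prev_day_large`, `four_year_large`), `value`,
#'   `fallback_used`.
#' @export
build_contrasts <- function(event, station, large_scale,
                            lat = 54.132, lon = 8.877, include_twc = TRUE) {
  stopifnot(nrow(event) == 1)
  day <- event_date(event)
  prev <- day - 1
  ref_years <- same_date_previous_years(day, 4)

  flight_dir <- if ("mean_direction" %in% names(event)) {
    event$mean_direction[1]
  } else {
    NA_real_
  }

  agg_local <- function(d) {
    sun <- sunrise_sunset(d, lat, lon)
    vals <- purrr::map_dbl(local_weather_vars(), function(v) {
      daylight_mean(station, sun, v)
    })
    names(vals) <- local_weather_vars()
    twc <- if (is.finite(flight_dir)) {
      ws <- vals[["wind_speed"]]; wd <- vals[["wind_direction"]]
      if (is.na(ws) || is.na(wd)) NA_real_ else
        tailwind_component(ws, wd, flight_dir)
    } else NA_real_
    c(vals, twc = twc)
  }
  agg_large <- function(d) {
    row <- large_scale[large_scale$date == d, , drop = FALSE]
    if (nrow(row) == 0) {
      setNames(rep(NA_real_, 4), large_weather_vars())
    } else {
      vals <- colMeans(row[large_weather_vars()])
      setNames(as.numeric(vals), large_weather_vars())
    }
  }

  day_local <- agg_local(day)
  prev_local <- agg_local(prev)
  fy_local_mat <- vapply(ref_years, agg_local, day_local)
  fy_local <- rowMeans(fy_local_mat)
  # circular variables are averaged circularly across the four years
  fy_local["wind_direction"] <- circular_mean_deg(fy_local_mat["wind_direction", ])

  day_large <- agg_large(day)
  prev_large <- agg_large(prev)
  fy_large <- rowMeans(vapply(ref_years, agg_large, day_large))

  one <- function(vname, condition, dv, rv) {
    ct <- contrast_value(dv, rv)
    tibble::tibble(variable = vname, condition = condition,
                   value = ct$value, fallback_used = ct$fallback_used)
  }
  lv <- local_weather_vars()
  out <- dplyr::bind_rows(
    purrr::map(lv, ~ one(.x, "prev_day_local", day_local[[.x]], prev_local[[.x]])),
    purrr::map(lv, ~ one(.x, "four_year_local", day_local[[.x]], fy_local[[.x]])),
    purrr::map(large_weather_vars(),
               ~ one(.x, "prev_day_large", day_large[[.x]], prev_large[[.x]])),
    purrr::map(large_weather_vars(),
               ~ one(.x, "four_year_large", day_large[[.x]], fy_large[[.x]]))
  )
  if (include_twc) {
    out <- dplyr::bind_rows(
      out,
      one("twc", "prev_day_local", day_local[["twc"]], prev_local[["twc"]]),
      one("twc", "four_year_local", day_local[["twc"]], fy_local[["twc"]])
    )
  }
  out
}

event_date <- function(event) {
  if ("timestamp" %in% names(event) && !is.na(event$timestamp[1])) {
    as.Date(event$timestamp[1], tz = "UTC")
  } else {
    as.Date(paste0(event$year[1], "-01-01")) + event$day_of_year[1] - 1
  }
}

# Same calendar date in the k preceding years; 29 Feb -> 28 Feb off-leap.
same_date_previous_years <- function(date, k) {
  mmdd <- format(date, "%m-%d")
  yr <- as.integer(format(date, "%Y"))
  purrr::map_vec(seq_len(k), function(i) {
    y <- yr - i
    d <- suppressWarnings(as.Date(paste0(y, "-", mmdd)))
    if (is.na(d)) d <- as.Date(paste0(y, "-02-28"))
    d
  })
}
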