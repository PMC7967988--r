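#' Read a Movebank-flavoured GPS fix CSV
#'
#' Expects the standard Movebank column names (`individual-local-identifier`,
#' `timestamp` as ISO-8601 UTC, `location-lat`, `location-long`,
#' `ground-speed` in m/s, `height-above-msl` in m); extra columns are
#' ignored. Ground speed is converted to km/h, the unit used throughout the
#' package. Timestamps must be strictly increasing per individual.
#'
#' @param path CSV file path.
#' @return A fix tibble: `individual_id`, `timestamp` (POSIXct UTC), `lat`,
#'   `lon`, `ground_speed` (km/h), `altitude` (m; NA when the device did not
#'   record it).
#' @export
read_fixes <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("individual-local-identifier", "timestamp", "location-lat",
            "location-long", "ground-speed")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("fix CSV ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    individual_id = as.character(raw[["individual-local-identifier"]]),
    timestamp = as.POSIXct(raw[["timestamp"]], tz = "UTC"),
    lat = raw[["location-lat"]],
    lon = raw[["location-long"]],
    ground_speed = raw[["ground-speed"]] * 3.6,
    altitude = if ("height-above-msl" %in% names(raw)) {
      raw[["height-above-msl"]]
    } else NA_real_
  )
  check_coords(out$lat, out$lon)
  dup <- out |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(bad = any(diff(as.numeric(.data$timestamp)) <= 0),
                     .groups = "drop")
  if (any(dup$bad)) {
    stop("timestamps are not strictly increasing for individual(s): ",
         paste(dup$individual_id[dup$bad], collapse = ", "), call. = FALSE)
  }
  out
}

#' Write fixes as Movebank-flavoured CSV
#'
#' @param fixes Fix tibble (see [read_fixes()] for columns; `ground_speed`
#'   in km/h is converted to m/s on disk).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path) {
  out <- tibble::tibble(
    `individual-local-identifier` = fixes$individual_id,
    timestamp = format(fixes$timestamp, "%Y-%m-%d %H:%M:%OS3", tz = "UTC"),
    `location-lat` = fixes$lat,
    `location-long` = fixes$lon,
    `ground-speed` = fixes$ground_speed / 3.6,
    `height-above-msl` = fixes$altitude %||% NA_real_
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read the 1-min weather-station CSV
#'
#' Validates the schema of the local station table: `timestamp` plus the
#' eight recorded variables (`temperature`, `wind_speed`, `wind_speed_max`,
#' `wind_direction`, `precipitation`, `global_radiation`, `air_pressure`,
#' `humidity`).
#'
#' @param path CSV file path.
#' @return A station tibble with UTC POSIXct timestamps.
#' @export
read_station_weather <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("timestamp", local_weather_vars())
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("station weather CSV ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw$timestamp <- as.POSIXct(raw$timestamp, tz = "UTC")
  if (any(raw$wind_direction < 0 | raw$wind_direction >= 360, na.rm = TRUE)) {
    stop("wind_direction must be in [0, 360)", call. = FALSE)
  }
  neg <- purrr::keep(c("wind_speed", "precipitation", "global_radiation"),
                     ~ any(raw[[.x]] < 0, na.rm = TRUE))
  if (length(neg)) {
    stop("negative values in non-negative variable(s): ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(raw)
}

#' Read the daily large-scale weather CSV
#'
#' One row per day per grid cell: `date`, `cell_lat`, `cell_lon`,
#' `temperature`, `pressure`, `wind_u` (eastward), `wind_v` (northward).
#'
#' @param path CSV file path.
#' @return A daily tibble with `Date` dates.
#' @export
read_large_weather <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("date", "cell_lat", "cell_lon", large_weather_vars())
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("large-scale weather CSV ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw$date <- as.Date(raw$date)
  tibble::as_tibble(raw)
}
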