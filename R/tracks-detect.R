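#' Detect the departure from the wintering site
#'
#' Migration departure is operationalised as the first instant at which
#' ground speed exceeds `speed_threshold` sustained for at least
#' `sustain_min` minutes AND net displacement from the wintering centroid
#' grows past `relocation_radius_km` within `confirm_hours`. Short
#' pre-departure relocations within the wintering area (always < 30 km in
#' the field data) therefore never qualify; the departure from the last
#' wintering-area site is the event.
#'
#' @param fixes Fix tibble for one individual-year (columns `timestamp`,
#'   `lat`, `lon`, `ground_speed` in km/h; extra columns ignored), ordered in
#'   time.
#' @param wintering_centroid Named vector `c(lat =, lon =)`.
#' @param speed_threshold Sustained-flight ground speed, km/h.
#' @param sustain_min Minimum duration of the fast bout, minutes.
#' @param relocation_radius_km Displacement that distinguishes migration from
#'   a within-area relocation.
#' @param confirm_hours Window in which that displacement must be reached.
#' @param corridor_box Optional `c(min_lat, max_lat, min_lon, max_lon)`; when
#'   given, the event's `mean_direction` is the circular mean bearing across
#'   the box, otherwise over the first two hours of flight.
#' @return A one-row events tibble (`individual_id`, `kind`, `year`,
#'   `day_of_year`, `time_of_day`, `mean_direction`, `timestamp`), or a
#'   zero-row tibble of the same shape when no departure is found.
#' @export
detect_departure <- function(fixes, wintering_centroid, speed_threshold = 20,
                             sustain_min = 30, relocation_radius_km = 30,
                             confirm_hours = 6, corridor_box = NULL) {
  fixes <- validate_fixes(fixes)
  if (nrow(fixes) < 3) return(empty_events())
  d <- great_circle_km(fixes$lat, fixes$lon,
                       wintering_centroid[["lat"]], wintering_centroid[["lon"]])
  fast <- fixes$ground_speed > speed_threshold
  starts <- bout_starts(fixes$timestamp, fast, sustain_min)
  for (i in starts) {
    if (d[i] > relocation_radius_km) next   # already away: not a departure
    w <- which(fixes$timestamp >= fixes$timestamp[i] &
                 fixes$timestamp <= fixes$timestamp[i] + confirm_hours * 3600)
    if (max(d[w]) <= relocation_radius_km) next
    # displacement must grow monotonically past the radius once it starts
    # increasing (a departure from a relocation site may first pass back
    # towards the wintering centroid); loops back into the wintering area
    # of more than 5 km disqualify the bout
    first_out <- which(d[w] > relocation_radius_km)[1]
    grow <- w[which.min(d[w[seq_len(first_out)]]):first_out]
    if (any(cummax(d[grow]) - d[grow] > 5)) next
    return(event_row(fixes, i, "departure", d, corridor_box))
  }
  empty_events()
}

#' Detect the arrival back at the wintering site
#'
#' The mirror of [detect_departure()]: the arrival is the instant at which
#' the bird, inbound in sustained flight from beyond the residency radius,
#' first comes within `residency_radius_km` of the wintering centroid and
#' then remains inside it (for at least `settle_hours`, or until the record
#' ends).
#'
#' @inheritParams detect_departure
#' @param residency_radius_km Radius of the wintering area, km.
#' @param settle_hours Time the bird must remain inside the radius.
#' @return A one-row events tibble, or a zero-row tibble when no arrival is
#'   found (e.g. transmitter death en route).
#' @export
detect_arrival <- function(fixes, wintering_centroid, speed_threshold = 20,
                           residency_radius_km = 30, settle_hours = 24,
                           corridor_box = NULL) {
  fixes <- validate_fixes(fixes)
  if (nrow(fixes) < 3) return(empty_events())
  d <- great_circle_km(fixes$lat, fixes$lon,
                       wintering_centroid[["lat"]], wintering_centroid[["lon"]])
  n <- nrow(fixes)
  # candidate crossings: outside -> inside
  cross <- which(d[-1] <= residency_radius_km & d[-n] > residency_radius_km) + 1
  for (i in cross) {
    # must have been truly away (not a wintering-area wobble): at least 24 h
    # spent beyond the radius before this crossing
    away <- fixes$timestamp[i] - fixes$timestamp[
      max(which(d[seq_len(i - 1)] <= residency_radius_km), 0) %+|% 1]
    if (is.na(away) || as.numeric(away, units = "hours") < 24) next
    # inbound by flight: fast fixes in the preceding hour
    pre <- which(fixes$timestamp >= fixes$timestamp[i] - 3600 &
                   fixes$timestamp <= fixes$timestamp[i])
    if (!any(fixes$ground_speed[pre] > speed_threshold)) next
    # stays inside
    post <- which(fixes$timestamp >= fixes$timestamp[i] &
                    fixes$timestamp <= fixes$timestamp[i] + settle_hours * 3600)
    if (any(d[post] > residency_radius_km)) next
    return(event_row(fixes, i, "arrival", d, corridor_box))
  }
  empty_events()
}

# index guard: max(which(...), 0) -> 1 when empty/zero
`%+|%` <- function(x, lo) if (length(x) == 0 || x < lo) lo else x

#' Detect departures and arrivals for every individual-year
#'
#' Splits a multi-individual, multi-year fix table by individual and UTC
#' calendar year and runs [detect_departure()] and [detect_arrival()] on each
#' slice.
#'
#' @param fixes Fix tibble with `individual_id`.
#' @inheritParams detect_departure
#' @inheritParams detect_arrival
#' @return An events tibble, one row per detected event.
#' @export
detect_events <- function(fixes, wintering_centroid, corridor_box = NULL,
                          speed_threshold = 20, sustain_min = 30,
                          relocation_radius_km = 30,
                          residency_radius_km = 30, settle_hours = 24) {
  fixes <- validate_fixes(fixes, require_id = TRUE)
  fixes$year <- as.integer(format(fixes$timestamp, "%Y", tz = "UTC"))
  fixes |>
    dplyr::group_by(.data$individual_id, .data$year) |>
    dplyr::group_map(function(g, key) {
      g$individual_id <- key$individual_id
      dplyr::bind_rows(
        detect_departure(g, wintering_centroid,
                         speed_threshold = speed_threshold,
                         sustain_min = sustain_min,
                         relocation_radius_km = relocation_radius_km,
                         corridor_box = corridor_box),
        detect_arrival(g, wintering_centroid,
                       speed_threshold = speed_threshold,
                       residency_radius_km = residency_radius_km,
                       settle_hours = settle_hours,
                       corridor_box = corridor_box)
      )
    }) |>
    dplyr::bind_rows()
}

validate_fixes <- function(fixes, require_id = FALSE) {
  need <- c("timestamp", "lat", "lon", "ground_speed")
  if (require_id) need <- c("individual_id", need)
  missing <- setdiff(need, names(fixes))
  if (length(missing)) {
    stop("fix table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_coords(fixes$lat, fixes$lon)
  if (is.unsorted(fixes$timestamp)) {
    fixes <- dplyr::arrange(fixes, .data$timestamp)
  }
  fixes
}

empty_events <- function() {
  tibble::tibble(individual_id = character(), kind = character(),
                 year = integer(), day_of_year = integer(),
                 time_of_day = character(), mean_direction = numeric(),
                 timestamp = as.POSIXct(character(), tz = "UTC"))
}

event_row <- function(fixes, i, kind, d, corridor_box) {
  t0 <- fixes$timestamp[i]
  dir <- if (!is.null(corridor_box)) {
    # corridor means are flight statistics: in-box fixes of the event's own
    # migration bout, not the residency scatter that may share the box
    win <- if (kind == "departure") c(t0, t0 + 48 * 3600) else
      c(t0 - 48 * 3600, t0 + 3600)
    bout <- fixes[fixes$timestamp >= win[1] & fixes$timestamp <= win[2] &
                    fixes$ground_speed > 20, , drop = FALSE]
    cs <- corridor_stats(bout, corridor_box)
    cs$mean_direction
  } else {
    w <- which(fixes$timestamp >= t0 - 3600 * (kind == "arrival") * 2 &
                 fixes$timestamp <= t0 + 7200)
    w <- w[fixes$ground_speed[w] > 20]
    if (length(w) >= 2) {
      b <- bearing_deg(fixes$lat[w[-length(w)]], fixes$lon[w[-length(w)]],
                       fixes$lat[w[-1]], fixes$lon[w[-1]])
      circular_mean_deg(b)
    } else NA_real_
  }
  tibble::tibble(
    individual_id = fixes$individual_id[i] %||% NA_character_,
    kind = kind,
    year = as.integer(format(t0, "%Y", tz = "UTC")),
    day_of_year = as.integer(strftime(t0, "%j", tz = "UTC")),
    time_of_day = format(t0, "%H:%M", tz = "UTC"),
    mean_direction = dir,
    timestamp = t0
  )
}

# Indices where a sustained fast bout starts: fast at the index and remaining
# fast for at least sustain_min minutes (by timestamps).
bout_starts <- function(ts, fast, sustain_min) {
  fast[is.na(fast)] <- FALSE
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- r$values &
    as.numeric(ts[ends] - ts[starts], units = "mins") >= sustain_min
  starts[ok]
}
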