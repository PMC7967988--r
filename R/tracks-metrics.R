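#' Curvature of a flight bout
#'
#' Relative deviation between the flown and the linear (great-circle)
#' distance, `100 * (flown - linear) / flown`, an indicator of how much the
#' realised flight line meanders. Only bouts logged at intervals of 5 min or
#' less are comparable; a bout containing a longer gap is not evaluable and
#' returns `NA`.
#'
#' @param bout Fix tibble of one flight bout (`timestamp`, `lat`, `lon`),
#'   ordered in time.
#' @param max_gap_min Longest permissible gap between fixes, minutes.
#' @return Curvature in percent (>= 0 up to numerical noise), or `NA` when
#'   the bout is not evaluable.
#' @export
curvature_pct <- function(bout, max_gap_min = 5) {
  if (nrow(bout) < 2) return(NA_real_)
  gaps <- diff(as.numeric(bout$timestamp)) / 60
  if (any(gaps > max_gap_min + 1e-9)) return(NA_real_)
  flown <- flown_km(bout$lat, bout$lon)
  if (flown == 0) return(NA_real_)
  linear <- great_circle_km(bout$lat[1], bout$lon[1],
                            bout$lat[nrow(bout)], bout$lon[nrow(bout)])
  100 * (flown - linear) / flown
}

#' Mean direction, speed and altitude across a corridor box
#'
#' Means over the fixes inside a latitude/longitude rectangle (the flight
#' corridor in which the tags log at their highest cadence): the mean
#' direction is the circular mean of successive-fix bearings, speed and
#' altitude are arithmetic means. Fewer than two in-box fixes is not
#' evaluable.
#'
#' @param fixes Fix tibble (`timestamp`, `lat`, `lon`, `ground_speed`,
#'   optionally `altitude`).
#' @param box Numeric `c(min_lat, max_lat, min_lon, max_lon)`.
#' @return A one-row tibble: `mean_direction` (deg), `mean_speed` (km/h),
#'   `mean_altitude` (m; `NA` when altitude is absent), `n_fixes`.
#' @export
corridor_stats <- function(fixes, box) {
  stopifnot(length(box) == 4, box[1] < box[2], box[3] < box[4])
  inb <- fixes$lat >= box[1] & fixes$lat <= box[2] &
    fixes$lon >= box[3] & fixes$lon <= box[4]
  g <- fixes[which(inb), , drop = FALSE]
  if (nrow(g) < 2) {
    return(tibble::tibble(mean_direction = NA_real_, mean_speed = NA_real_,
                          mean_altitude = NA_real_, n_fixes = nrow(g)))
  }
  g <- g[order(g$timestamp), ]
  n <- nrow(g)
  b <- bearing_deg(g$lat[-n], g$lon[-n], g$lat[-1], g$lon[-1])
  tibble::tibble(
    mean_direction = circular_mean_deg(b),
    mean_speed = mean(g$ground_speed),
    mean_altitude = if ("altitude" %in% names(g) && !all(is.na(g$altitude))) {
      mean(g$altitude, na.rm = TRUE)
    } else NA_real_,
    n_fixes = n
  )
}

#' First-stop fraction of the migration distance
#'
#' Share of the total wintering-to-breeding linear distance covered by the
#' first migration bout, in percent: `100 * first_stop_km / linear_km`.
#' On the field means (first stop 775.8 km, linear migration distance
#' 2339 km) this is about a third.
#'
#' @param first_stop_km Mean linear distance to the first stop-over, km.
#' @param linear_km Mean linear wintering-to-breeding distance, km.
#' @return Percentage (numeric).
#' @export
first_stop_fraction <- function(first_stop_km, linear_km) {
  if (any(linear_km <= 0) || any(first_stop_km < 0)) {
    stop("distances must be positive", call. = FALSE)
  }
  100 * first_stop_km / linear_km
}

#' Track metrics for one individual-year
#'
#' Convenience wrapper combining [classify_sites()] and [first_stop()] into
#' the per-event metric set used as constant predictors downstream: linear
#' wintering-to-breeding distance, linear and flown distance to the first
#' stop, curvature, flight time and first-stop duration.
#'
#' @inheritParams detect_departure
#' @param departure One-row events tibble.
#' @return A one-row tibble of metrics (NAs when the breeding site is
#'   unresolved).
#' @export
track_metrics <- function(fixes, departure, wintering_centroid, ...) {
  sites <- classify_sites(fixes, wintering_centroid, ...)
  breeding <- sites[sites$kind == "breeding", , drop = FALSE]
  fs <- first_stop(fixes, departure, sites, wintering_centroid)
  tibble::tibble(
    linear_distance_km = if (nrow(breeding)) breeding$distance_km else NA_real_,
    breeding_lat = if (nrow(breeding)) breeding$lat else NA_real_,
    linear_to_first_stop_km = fs$linear_km,
    flown_to_first_stop_km = fs$flown_km,
    curvature_pct = fs$curvature_pct,
    flight_time_h = fs$flight_time_h,
    first_stop_duration_d = fs$stop_duration_d
  )
}
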