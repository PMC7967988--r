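#' Simulate departure events at the event level
#'
#' Generates a departure-event dataset with known ground truth for studying
#' the driver screen itself: a roster of individuals with breeding sites,
#' one departure event per individual-year with the planted day-of-year
#' model (distance and latitude slopes, individual random intercept,
#' residual noise), 24 null weather contrasts (and 2 null TWC contrasts)
#' drawn as quotients around 1 with no relation to the outcome, and null
#' first-stop/track predictors. This is the acceptance surface for the
#' LASSO + mixed-model stage: everything except breeding distance and
#' latitude is noise by construction.
#'
#' @param config A [sim_config()]; the planted slopes, sigmas and seed are
#'   taken from it.
#' @param n_events Total number of departure events to generate (events per
#'   individual follow from `config$years` coverage).
#' @return A list with `events`, `contrasts`, `track_metrics`, `roster`
#'   (ready for [build_matrix()]) and `truth` (the planted parameters).
#' @export
simulate_driver_events <- function(config, n_events = 80) {
  stopifnot(inherits(config, "sim_config"))
  roster <- generate_roster(config)
  withr::with_seed(derive_seed(config$seed, "driver_events"), {
    # draw individual-years until n_events reached, cycling the roster
    idx <- sort(rep_len(seq_len(nrow(roster)), n_events))
    ev <- roster[idx, ]
    ev$year <- as.integer(stats::ave(idx, idx, FUN = seq_along)) +
      min(config$years) - 1L
    doy <- config$base_departure_doy +
      config$beta_distance * (ev$distance_km - config$ref_distance_km) +
      config$beta_latitude * (ev$breeding_lat - config$ref_latitude) +
      ev$intercept_days + rnorm(n_events, 0, config$sigma_noise)
    events <- tibble::tibble(
      individual_id = ev$individual_id,
      year = as.integer(ev$year),
      kind = "departure",
      day_of_year = doy,
      time_of_day = sprintf("%02d:%02d",
                            sample(config$departure_window_utc[1]:
                                     (config$departure_window_utc[2] - 1),
                                   n_events, replace = TRUE),
                            sample(0:59, n_events, replace = TRUE)),
      mean_direction = (bearing_deg(config$wintering_site[["lat"]],
                                    config$wintering_site[["lon"]],
                                    ev$breeding_lat, ev$breeding_lon) +
                          rnorm(n_events, 0, 4)) %% 360
    )

    vars <- tibble::tibble(
      variable = c(rep(local_weather_vars(), 2), rep(large_weather_vars(), 2),
                   "twc", "twc"),
      condition = c(rep(c("prev_day_local", "four_year_local"),
                        each = length(local_weather_vars())),
                    rep(c("prev_day_large", "four_year_large"),
                        each = length(large_weather_vars())),
                    "prev_day_local", "four_year_local")
    )
    contrasts <- tidyr::crossing(
      events[, c("individual_id", "year")], vars) |>
      dplyr::mutate(value = exp(rnorm(dplyr::n(), 0, 0.15)),
                    fallback_used = FALSE)

    track_metrics <- tibble::tibble(
      individual_id = events$individual_id,
      year = events$year,
      linear_distance_km = ev$distance_km,
      breeding_lat = ev$breeding_lat,
      linear_to_first_stop_km = runif(n_events, 400, 1200),
      flown_to_first_stop_km = NA_real_,
      curvature_pct = runif(n_events, 0, 12),
      flight_time_h = runif(n_events, 6, 20),
      first_stop_duration_d = runif(n_events, 2, 10)
    )
    track_metrics$flown_to_first_stop_km <-
      track_metrics$linear_to_first_stop_km * (1 + runif(n_events, 0, 0.1))

    list(events = events, contrasts = contrasts,
         track_metrics = track_metrics, roster = roster,
         truth = list(beta_distance = config$beta_distance,
                      beta_latitude = config$beta_latitude,
                      null_predictors = setdiff(
                        contrast_col_names(), character(0)),
                      planted = c("linear_distance_km", "breeding_lat")))
  })
}
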