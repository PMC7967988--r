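#' Configuration for the synthetic track-and-weather generator
#'
#' Bundles every knob of the simulator into a validated list. The defaults
#' describe a Wadden Sea wintering population of curlews migrating to
#' Arctic/sub-Arctic Russian breeding grounds: evening departures in
#' mid-to-late April, a first stop-over roughly a third of the way along the
#' route, a 47--62 day breeding residency, and a return leg in early summer.
#' Identical configurations (including `seed`) yield byte-identical tracks,
#' weather and ground truth.
#'
#' @param n_individuals Number of tagged individuals.
#' @param years Calendar years covered by the simulation. Each individual is
#'   tracked for a consecutive run of one or more of these years, so repeat
#'   migrations of the same bird arise naturally.
#' @param seed Integer seed governing every random draw.
#' @param wintering_site Named vector `c(lat =, lon =)`: the shared wintering
#'   centroid (decimal degrees).
#' @param breeding_lat_range,breeding_lon_range Uniform sampling ranges for
#'   breeding-site coordinates (degrees N / E).
#' @param base_departure_doy Population mean departure day-of-year at the
#'   reference breeding distance/latitude (default 108, 18 April).
#' @param beta_distance Planted departure-timing slope, days per km of linear
#'   wintering-to-breeding distance (later departure when breeding farther).
#' @param beta_latitude Planted slope, days per degree of breeding latitude.
#' @param ref_distance_km,ref_latitude Centring constants for the two planted
#'   slopes (effects are zero at the reference values).
#' @param sigma_individual SD (days) of the per-individual random intercept in
#'   departure timing.
#' @param sigma_noise Residual SD (days) of departure timing within
#'   individual.
#' @param departure_window_utc Two UTC hours; the departure instant falls in
#'   this evening window (curlews leave around and after sunset).
#' @param airspeed_mean Mean airspeed in km/h; realised ground speed is
#'   `airspeed + twc_speed_gain * 3.6 * TWC` with TWC in m/s.
#' @param airspeed_sd Between-flight SD of airspeed (km/h).
#' @param twc_speed_gain Dimensionless wind-support gain on ground speed
#'   (1 = full drift of the tailwind component).
#' @param altitude_base Flight altitude (m a.s.l.) under neutral wind.
#' @param altitude_headwind_slope Planted altitude response, metres per m/s of
#'   headwind (i.e. per unit of negative tailwind component).
#' @param fix_interval GPS cadence during flight bouts, minutes (devices log
#'   at pre-programmed intervals of 1--15 min).
#' @param residency_interval GPS cadence during residency, minutes.
#' @param breeding_stay_range Days spent at the breeding site, drawn uniformly
#'   from this range (field range 47--62 days).
#' @param first_stop_fraction Fraction of the total route flown before the
#'   first stop-over (about one third in the field data).
#' @param p_relocation Probability of a short (< 30 km) pre-departure
#'   relocation within the wintering area.
#' @param p_lost_return Probability that the transmitter dies before the
#'   return leg, producing a departure-only track.
#' @param jitter_m SD of Gaussian positional jitter on every fix, metres.
#' @param wind_regime A list: `list(type = "stochastic", prevailing_dir = 240,
#'   mean_speed = 6)` for synoptic variability, or
#'   `list(type = "constant", dir = , speed = )` for a fixed wind, or
#'   `list(type = "calm")` for zero wind.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 23,
                       years = 2016:2018,
                       seed = 1L,
                       wintering_site = c(lat = 54.0, lon = 8.85),
                       breeding_lat_range = c(55, 70),
                       breeding_lon_range = c(20, 65),
                       base_departure_doy = 108,
                       beta_distance = 0.01,
                       beta_latitude = 1,
                       ref_distance_km = 2339,
                       ref_latitude = 62.5,
                       sigma_individual = 3,
                       sigma_noise = 2.5,
                       departure_window_utc = c(18, 22),
                       airspeed_mean = 65,
                       airspeed_sd = 6,
                       twc_speed_gain = 1,
                       altitude_base = 900,
                       altitude_headwind_slope = 150,
                       fix_interval = 5,
                       residency_interval = 15,
                       breeding_stay_range = c(47, 62),
                       first_stop_fraction = 0.33,
                       p_relocation = 0.3,
                       p_lost_return = 0.15,
                       jitter_m = 50,
                       wind_regime = list(type = "stochastic",
                                          prevailing_dir = 240,
                                          mean_speed = 6)) {
  cfg <- as.list(environment())
  check_range <- function(x, name) {
    if (length(x) != 2 || x[1] > x[2]) {
      stop("invalid ", name, ": min must not exceed max", call. = FALSE)
    }
  }
  if (cfg$n_individuals < 1) stop("n_individuals must be >= 1", call. = FALSE)
  if (length(cfg$years) < 1) stop("years must be non-empty", call. = FALSE)
  check_range(cfg$breeding_lat_range, "breeding_lat_range")
  check_range(cfg$breeding_lon_range, "breeding_lon_range")
  check_range(cfg$breeding_stay_range, "breeding_stay_range")
  check_range(cfg$departure_window_utc, "departure_window_utc")
  if (cfg$fix_interval < 1 || cfg$fix_interval > 15) {
    stop("fix_interval must be in [1, 15] minutes", call. = FALSE)
  }
  if (cfg$sigma_individual < 0 || cfg$sigma_noise < 0) {
    stop("sigma_individual and sigma_noise must be non-negative", call. = FALSE)
  }
  if (!cfg$wind_regime$type %in% c("stochastic", "constant", "calm")) {
    stop("wind_regime$type must be 'stochastic', 'constant' or 'calm'",
         call. = FALSE)
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# Deterministic sub-seed for a named simulation stream, always < 2^31.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

#' Generate a roster of tagged individuals
#'
#' Draws each individual's sex, catching location, breeding site, random
#' departure-timing intercept, and the consecutive run of years in which it
#' was tracked. The default population mirrors a near-even sex ratio
#' (`floor(n/2)` females).
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per individual: `individual_id`, `sex`
#'   ("F"/"M"), `catching_location`, `breeding_lat`, `breeding_lon`,
#'   `distance_km` (great-circle wintering to breeding), `intercept_days`,
#'   `first_year`, `n_years`.
#' @export
generate_roster <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  withr::with_seed(derive_seed(config$seed, "roster"), {
    n_f <- floor(n / 2)
    sex <- sample(rep(c("F", "M"), c(n_f, n - n_f)))
    blat <- runif(n, config$breeding_lat_range[1], config$breeding_lat_range[2])
    blon <- runif(n, config$breeding_lon_range[1], config$breeding_lon_range[2])
    ws <- config$wintering_site
    intercept <- rnorm(n, 0, config$sigma_individual)
    # sample() would misread a single year as 1:year
    first_year <- config$years[sample.int(length(config$years), n,
                                          replace = TRUE)]
    max_span <- max(config$years) - first_year + 1
    n_years <- pmin(max_span, 1 + stats::rgeom(n, 0.45))
    tibble::tibble(
      individual_id = sprintf("C%02d", seq_len(n)),
      sex = sex,
      catching_location = sample(c("SH", "LS"), n, replace = TRUE,
                                 prob = c(0.7, 0.3)),
      breeding_lat = blat,
      breeding_lon = blon,
      distance_km = great_circle_km(ws["lat"], ws["lon"], blat, blon),
      intercept_days = intercept,
      first_year = first_year,
      n_years = n_years
    )
  })
}
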