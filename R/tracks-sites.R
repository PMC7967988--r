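#' Classify residency sites along a track
#'
#' Groups time-ordered fixes into residency clusters (a fix joins the current
#' cluster while it lies within `cluster_radius_km` of the cluster's running
#' centroid) and labels them. The breeding site is the cluster that (a) lies
#' farthest from the wintering centroid among clusters with (b) a stay of at
#' least `breeding_min_stay_d` days and (c) non-directional movement
#' (straightness index, net displacement over path length, below
#' `directionality_cutoff`); the distance rule dominates among qualifying
#' clusters. Clusters between the wintering area and the breeding site are
#' stop-overs. Exactly one breeding site is returned per individual-year, or
#' none with attribute `breeding_unresolved = TRUE` when no cluster satisfies
#' the rule.
#'
#' @inheritParams detect_departure
#' @param cluster_radius_km Radius of the running-centroid clustering.
#' @param min_stay_d Minimum stay for a cluster to count as a site at all.
#' @param breeding_min_stay_d Minimum stay for the breeding rule ("several
#'   weeks"; observed field range 47--62 days, so 21 is conservative).
#' @param directionality_cutoff Straightness index below which movement
#'   within a cluster counts as non-directional.
#' @return A sites tibble: `kind` (wintering/stopover/breeding), `lat`,
#'   `lon` (centroid = arithmetic mean of member positions), `first_fix`,
#'   `last_fix`, `duration_d`, `distance_km` (from the wintering centroid),
#'   `n_fixes`; attribute `breeding_unresolved` when no breeding site
#'   qualified.
#' @export
classify_sites <- function(fixes, wintering_centroid, cluster_radius_km = 30,
                           min_stay_d = 1, breeding_min_stay_d = 21,
                           directionality_cutoff = 0.3) {
  fixes <- validate_fixes(fixes)
  cl <- running_centroid_clusters(fixes, cluster_radius_km)
  sites <- cl |>
    dplyr::filter(.data$duration_d >= min_stay_d)
  if (nrow(sites) == 0) {
    out <- sites_schema()
    attr(out, "breeding_unresolved") <- TRUE
    return(out)
  }
  sites$distance_km <- great_circle_km(sites$lat, sites$lon,
                                       wintering_centroid[["lat"]],
                                       wintering_centroid[["lon"]])
  qual <- sites$duration_d >= breeding_min_stay_d &
    sites$straightness < directionality_cutoff &
    sites$distance_km > cluster_radius_km
  breeding_idx <- if (any(qual)) {
    which(qual)[which.max(sites$distance_km[qual])]
  } else {
    NA_integer_
  }

  sites$kind <- dplyr::case_when(
    sites$distance_km <= cluster_radius_km ~ "wintering",
    seq_len(nrow(sites)) == breeding_idx ~ "breeding",
    TRUE ~ "stopover"
  )
  out <- sites[, c("kind", "lat", "lon", "first_fix", "last_fix",
                   "duration_d", "distance_km", "n_fixes")]
  if (is.na(breeding_idx)) {
    attr(out, "breeding_unresolved") <- TRUE
    message("breeding site unresolved: no cluster satisfies the ",
            "distance/duration/directionality rule")
  }
  out
}

sites_schema <- function() {
  tibble::tibble(kind = character(), lat = numeric(), lon = numeric(),
                 first_fix = as.POSIXct(character(), tz = "UTC"),
                 last_fix = as.POSIXct(character(), tz = "UTC"),
                 duration_d = numeric(), distance_km = numeric(),
                 n_fixes = integer())
}

# Sequential clustering against a running centroid. Returns one row per
# cluster with centroid (arithmetic mean of member positions), span and a
# straightness index (net displacement / path length within the cluster).
running_centroid_clusters <- function(fixes, radius_km) {
  n <- nrow(fixes)
  cluster_id <- integer(n)
  cid <- 1L
  c_lat <- fixes$lat[1]; c_lon <- fixes$lon[1]; c_n <- 1L
  cluster_id[1] <- cid
  for (i in seq_len(n)[-1]) {
    if (great_circle_km(fixes$lat[i], fixes$lon[i], c_lat, c_lon) <= radius_km) {
      c_n <- c_n + 1L
      c_lat <- c_lat + (fixes$lat[i] - c_lat) / c_n
      c_lon <- c_lon + (fixes$lon[i] - c_lon) / c_n
    } else {
      cid <- cid + 1L
      c_lat <- fixes$lat[i]; c_lon <- fixes$lon[i]; c_n <- 1L
    }
    cluster_id[i] <- cid
  }
  fixes$.cluster <- cluster_id
  fixes |>
    dplyr::group_by(.data$.cluster) |>
    dplyr::summarise(
      lat = mean(.data$lat),
      lon = mean(.data$lon),
      first_fix = min(.data$timestamp),
      last_fix = max(.data$timestamp),
      duration_d = as.numeric(max(.data$timestamp) - min(.data$timestamp),
                              units = "days"),
      n_fixes = dplyr::n(),
      straightness = straightness_index(.data$lat, .data$lon),
      .groups = "drop"
    ) |>
    dplyr::select(-".cluster")
}

# Net displacement over path length; 0 for perfectly non-directional
# scatter, 1 for a straight transit. Single-fix clusters count as 0.
straightness_index <- function(lat, lon) {
  n <- length(lat)
  if (n < 3) return(0)
  path <- sum(great_circle_km(lat[-n], lon[-n], lat[-1], lon[-1]))
  if (path == 0) return(0)
  great_circle_km(lat[1], lon[1], lat[n], lon[n]) / path
}

#' First stop-over after departure, with bout metrics
#'
#' Identifies the first classified site more than `exclusion_km` (30 km, the
#' pre-departure relocation limit) from the wintering centroid entered after
#' the departure instant; when the bird flew nonstop to the breeding site,
#' the breeding site is the first stop. Returns the site together with the
#' metrics of the first migration bout: linear (great-circle) distance from
#' the wintering centroid to the stop, flown distance accumulated along the
#' fixes, flight time, stop duration, and the track curvature of the bout.
#'
#' @inheritParams detect_departure
#' @param departure One-row events tibble from [detect_departure()].
#' @param sites Sites tibble from [classify_sites()].
#' @param exclusion_km Sites nearer than this are wintering-area moves, not
#'   stop-overs.
#' @return A one-row tibble: `kind`, `lat`, `lon`, `linear_km`, `flown_km`,
#'   `flight_time_h`, `stop_duration_d`, `curvature_pct` (NA when the bout
#'   has a gap over the curvature rule's 5-min limit).
#' @export
first_stop <- function(fixes, departure, sites, wintering_centroid,
                       exclusion_km = 30) {
  stopifnot(nrow(departure) == 1)
  fixes <- validate_fixes(fixes)
  cand <- sites[sites$kind %in% c("stopover", "breeding") &
                  sites$distance_km > exclusion_km &
                  sites$first_fix > departure$timestamp, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(tibble::tibble(kind = NA_character_, lat = NA_real_,
                          lon = NA_real_, linear_km = NA_real_,
                          flown_km = NA_real_, flight_time_h = NA_real_,
                          stop_duration_d = NA_real_,
                          curvature_pct = NA_real_))
  }
  s <- cand[which.min(cand$first_fix), ]
  bout <- fixes[fixes$timestamp >= departure$timestamp &
                  fixes$timestamp <= s$first_fix, , drop = FALSE]
  # anchor the flown path at the two site centroids so that flown and linear
  # distances share endpoints (flown >= linear by the triangle inequality)
  flown <- flown_km(c(wintering_centroid[["lat"]], bout$lat, s$lat),
                    c(wintering_centroid[["lon"]], bout$lon, s$lon))
  tibble::tibble(
    kind = s$kind, lat = s$lat, lon = s$lon,
    linear_km = s$distance_km,
    flown_km = flown,
    flight_time_h = as.numeric(s$first_fix - departure$timestamp,
                               units = "hours"),
    stop_duration_d = s$duration_d,
    curvature_pct = curvature_pct(bout)
  )
}

flown_km <- function(lat, lon) {
  n <- length(lat)
  if (n < 2) return(0)
  sum(great_circle_km(lat[-n], lon[-n], lat[-1], lon[-1]))
}
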