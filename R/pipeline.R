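#' Tag load as a percentage of body mass
#'
#' Device mass over body mass, in percent rounded to one decimal, with a
#' flag when the load exceeds the 3% welfare threshold recommended for
#' tracking devices.
#'
#' @param device_mass_g Device mass in grams (> 0).
#' @param body_mass_g Body mass in grams (> 0).
#' @param threshold_pct Flag threshold (strictly greater fires the flag).
#' @return A one-row tibble: `load_pct`, `exceeds_threshold`.
#' @examples
#' tag_load_pct(20, 827.8)   # heaviest logger on the mean male body mass
#' @export
tag_load_pct <- function(device_mass_g, body_mass_g, threshold_pct = 3) {
  if (any(device_mass_g <= 0) || any(body_mass_g <= 0)) {
    stop("masses must be positive", call. = FALSE)
  }
  pct <- round(100 * device_mass_g / body_mass_g, 1)
  tibble::tibble(load_pct = pct, exceeds_threshold = pct > threshold_pct)
}

#' Pipeline configuration
#'
#' Collects file paths, detector thresholds, the corridor box, contrast and
#' screening settings and the seed into one validated list. `fixes`,
#' `station` and `large_scale` may be file paths (CSV, read with the
#' package readers) or in-memory tibbles; leave them `NULL` to simulate
#' everything from `sim` (a [sim_config()]).
#'
#' @param fixes,station,large_scale Inputs (paths or tibbles), or `NULL`.
#' @param sim A [sim_config()] used when inputs are `NULL` (and as the
#'   source of the wintering centroid).
#' @param corridor_box `c(min_lat, max_lat, min_lon, max_lon)`.
#' @param wintering_centroid Named `c(lat =, lon =)`; defaults to the
#'   simulation's wintering site.
#' @param speed_threshold,sustain_min,relocation_radius_km Detector
#'   settings, see [detect_departure()].
#' @param k_folds,alpha LASSO/confirmation settings.
#' @param seed Integer seed for every random draw in the run.
#' @param out_dir Output directory for [run_pipeline()] artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fixes = NULL, station = NULL, large_scale = NULL,
                            sim = sim_config(),
                            corridor_box = c(53.4, 55.5, 8.2, 12.5),
                            wintering_centroid = NULL,
                            speed_threshold = 20, sustain_min = 30,
                            relocation_radius_km = 30,
                            k_folds = 5, alpha = 0.01,
                            seed = 1L, out_dir = tempfile("migratimer-run-")) {
  if (length(corridor_box) != 4 || corridor_box[1] >= corridor_box[2] ||
      corridor_box[3] >= corridor_box[4]) {
    stop("corridor_box must be c(min_lat, max_lat, min_lon, max_lon) with ",
         "min < max", call. = FALSE)
  }
  if (speed_threshold <= 0 || sustain_min <= 0 || relocation_radius_km <= 0) {
    stop("detector thresholds must be positive", call. = FALSE)
  }
  wintering_centroid <- wintering_centroid %||% sim$wintering_site
  structure(list(fixes = fixes, station = station, large_scale = large_scale,
                 sim = sim, corridor_box = corridor_box,
                 wintering_centroid = wintering_centroid,
                 speed_threshold = speed_threshold, sustain_min = sustain_min,
                 relocation_radius_km = relocation_radius_km,
                 k_folds = k_folds, alpha = alpha, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may hold any [pipeline_config()] field at top level plus a `sim`
#' block of [sim_config()] fields; unknown keys are refused. Thresholds that
#' are ambiguous in the field protocol (speed threshold, relocation radius,
#' cluster settings) all live here.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  bad <- setdiff(names(sim_args), names(formals(sim_config)))
  if (length(bad)) {
    stop("unknown sim config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(sim_args$wintering_site)) {
    sim_args$wintering_site <- unlist(sim_args$wintering_site)
  }
  raw$sim <- NULL
  bad <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(bad)) {
    stop("unknown pipeline config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$corridor_box)) raw$corridor_box <- unlist(raw$corridor_box)
  if (!is.null(raw$wintering_centroid)) {
    raw$wintering_centroid <- unlist(raw$wintering_centroid)
  }
  raw$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, raw)
}

#' Run the full migration-timing pipeline
#'
#' End to end: load (or simulate) fixes and weather, detect departures and
#' arrivals per individual-year, classify sites and compute first-stop/track
#' metrics, build the daylight-window weather contrasts and the 38-predictor
#' matrix, run the LASSO screen with confirmatory mixed model, and compute
#' the repeatability statistics. Writes `events.csv`, `sites.csv`,
#' `predictors.csv`, `drivers_report.csv`, `repeatability.csv` and
#' `run_log.txt` to `config$out_dir`; deterministic given the seed. Any
#' stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate result and the log
#'   lines.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    log <<- c(log, paste0(...))
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  sim <- config$sim
  sim$seed <- config$seed
  sim <- do.call(sim_config, sim[setdiff(names(sim), character(0))])
  wc <- config$wintering_centroid

  truth <- NULL
  inputs <- stage("load", {
    if (is.null(config$fixes)) {
      note("simulating roster and tracks (seed ", config$seed, ")")
      roster <- generate_roster(sim)
      trk <- simulate_tracks(roster, sim)
      truth <- trk$truth
      list(fixes = trk$fixes, station = NULL, large_scale = NULL,
           roster = roster)
    } else {
      fx <- if (is.character(config$fixes)) read_fixes(config$fixes) else
        validate_fixes(config$fixes, require_id = TRUE)
      st <- if (is.character(config$station)) {
        read_station_weather(config$station)
      } else config$station
      lg <- if (is.character(config$large_scale)) {
        read_large_weather(config$large_scale)
      } else config$large_scale
      roster <- fx |>
        dplyr::distinct(.data$individual_id) |>
        dplyr::mutate(sex = NA_character_, catching_location = "unknown")
      list(fixes = fx, station = st, large_scale = lg, roster = roster)
    }
  })
  note("fixes: ", nrow(inputs$fixes), " rows, ",
       dplyr::n_distinct(inputs$fixes$individual_id), " individuals")

  events <- stage("detect", {
    detect_events(inputs$fixes, wc, corridor_box = config$corridor_box,
                  speed_threshold = config$speed_threshold,
                  sustain_min = config$sustain_min,
                  relocation_radius_km = config$relocation_radius_km)
  })
  note("events: ", sum(events$kind == "departure"), " departures, ",
       sum(events$kind == "arrival"), " arrivals")

  per_iy <- stage("sites", {
    inputs$fixes |>
      dplyr::mutate(year = as.integer(format(.data$timestamp, "%Y",
                                             tz = "UTC"))) |>
      dplyr::group_by(.data$individual_id, .data$year) |>
      dplyr::group_map(function(g, key) {
        g$individual_id <- key$individual_id
        dep <- events[events$individual_id == key$individual_id &
                        events$year == key$year &
                        events$kind == "departure", ]
        sites <- classify_sites(g, wc)
        sites$individual_id <- key$individual_id
        sites$year <- key$year
        metrics <- NULL
        if (nrow(dep) == 1) {
          metrics <- track_metrics(g, dep, wc)
          metrics$individual_id <- key$individual_id
          metrics$year <- key$year
        }
        list(sites = sites, metrics = metrics)
      })
  })
  sites <- dplyr::bind_rows(purrr::map(per_iy, "sites"))
  metrics <- dplyr::bind_rows(purrr::map(per_iy, "metrics"))
  note("sites: ", nrow(sites), " (",
       sum(sites$kind == "breeding"), " breeding)")

  contrasts <- stage("weather", {
    deps <- events[events$kind == "departure", ]
    if (is.null(inputs$station)) {
      # simulated run: station/large-scale series for the event days, their
      # previous days and the same-date windows of the 4 preceding years
      ref_dates <- purrr::map(as.list(as.Date(deps$timestamp, tz = "UTC")),
                              function(d) c(d, d - 1,
                                            same_date_previous_years(d, 4)))
      wx <- simulate_weather(sim, dates = sort(unique(do.call(c, ref_dates))))
      inputs$station <- wx$station
      inputs$large_scale <- wx$large_scale
    }
    purrr::map(seq_len(nrow(deps)), function(i) {
      ct <- build_contrasts(deps[i, ], inputs$station, inputs$large_scale,
                            lat = wc[["lat"]], lon = wc[["lon"]])
      ct$individual_id <- deps$individual_id[i]
      ct$year <- deps$year[i]
      ct
    }) |> dplyr::bind_rows()
  })
  note("contrasts: ", nrow(contrasts), " rows (",
       sum(is.na(contrasts$value)), " missing)")

  drivers <- stage("drivers", {
    deps <- events[events$kind == "departure", ]
    pm <- build_matrix(deps, contrasts, metrics, inputs$roster)
    note("predictor matrix: ", nrow(pm), " x ",
         length(attr(pm, "predictors")), " (", attr(pm, "dropped"),
         " rows dropped)")
    screen_drivers(pm, k_folds = config$k_folds, seed = config$seed,
                   alpha = config$alpha)
  })
  note("drivers: ", length(drivers$selected), " selected, ",
       sum(drivers$coefficients$significant), " significant at p < ",
       config$alpha)

  repeat_tbl <- stage("repeatability", {
    dep_rec <- events |>
      dplyr::filter(.data$kind == "departure") |>
      dplyr::select("individual_id", "year", value = "day_of_year")
    arr_rec <- events |>
      dplyr::filter(.data$kind == "arrival") |>
      dplyr::select("individual_id", "year", value = "day_of_year")
    dir_rec <- events |>
      dplyr::filter(.data$kind == "departure") |>
      dplyr::select("individual_id", "year", value = "mean_direction")
    dplyr::bind_rows(
      dplyr::mutate(mean_abs_diff(dep_rec), metric = "departure_day"),
      dplyr::mutate(mean_abs_diff(arr_rec), metric = "arrival_day"),
      dplyr::rename(dplyr::mutate(direction_repeatability(dir_rec),
                                  metric = "departure_direction"),
                    mean_abs_diff = "mean_circ_diff",
                    sd_abs_diff = "sd_circ_diff")
    )
  })
  note("repeatability: ", paste(repeat_tbl$metric, "n_pairs",
                                repeat_tbl$n_pairs, collapse = "; "))

  stage("write", {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) readr::write_csv(x, file.path(config$out_dir, f),
                                         progress = FALSE)
    w(events, "events.csv")
    w(sites, "sites.csv")
    w(contrasts, "predictors.csv")
    w(tidy(drivers), "drivers_report.csv")
    w(repeat_tbl, "repeatability.csv")
    writeLines(c(paste("migratimer", as.character(utils::packageVersion("migratimer"))),
                 paste("seed", config$seed), log),
               file.path(config$out_dir, "run_log.txt"))
  })

  invisible(list(events = events, sites = sites, metrics = metrics,
                 contrasts = contrasts, drivers = drivers,
                 repeatability = repeat_tbl, truth = truth,
                 roster = inputs$roster, log = log,
                 out_dir = config$out_dir))
}
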