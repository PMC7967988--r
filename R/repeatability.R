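#' Intra-individual repeatability of migration timing
#'
#' Mean absolute difference of a yearly value (typically departure or
#' arrival day-of-year) between consecutive tracked years of the same
#' individual, pooled over all such pairs. Differences are computed within
#' individuals before pooling ("individually standardised"); a z-scored
#' variant (values centred and scaled within individual before differencing)
#' is available behind `standardize`. A missing middle year breaks the pair
#' chain: only year pairs with a gap of exactly one are used.
#'
#' @param records Tibble with `individual_id`, `year` and `value`.
#' @param standardize "none" (default: raw within-individual differences) or
#'   "zscore".
#' @return A one-row tibble: `mean_abs_diff`, `sd_abs_diff`, `n_pairs`,
#'   `n_individuals`. All-`NA` (with a message) when no individual has two
#'   consecutive years.
#' @export
mean_abs_diff <- function(records, standardize = c("none", "zscore")) {
  standardize <- match.arg(standardize)
  pairs <- consecutive_pairs(records)
  if (nrow(pairs) == 0) {
    message("repeatability not evaluable: no individual with consecutive years")
    return(tibble::tibble(mean_abs_diff = NA_real_, sd_abs_diff = NA_real_,
                          n_pairs = 0L, n_individuals = 0L))
  }
  if (standardize == "zscore") {
    z <- records |>
      dplyr::group_by(.data$individual_id) |>
      dplyr::mutate(value = (.data$value - mean(.data$value)) /
                      ifelse(sd(.data$value) > 0, sd(.data$value), 1)) |>
      dplyr::ungroup()
    pairs <- consecutive_pairs(z)
  }
  d <- abs(pairs$value2 - pairs$value1)
  tibble::tibble(mean_abs_diff = mean(d),
                 sd_abs_diff = if (length(d) > 1) sd(d) else NA_real_,
                 n_pairs = length(d),
                 n_individuals = dplyr::n_distinct(pairs$individual_id))
}

#' Repeatability of flight direction
#'
#' As [mean_abs_diff()] but on circular values: the per-pair difference is
#' the shortest arc between the two directions, so results lie in
#' \[0, 180\] degrees.
#'
#' @param records Tibble with `individual_id`, `year` and `value` (degrees).
#' @return A one-row tibble: `mean_circ_diff`, `sd_circ_diff`, `n_pairs`,
#'   `n_individuals`.
#' @export
direction_repeatability <- function(records) {
  pairs <- consecutive_pairs(records)
  if (nrow(pairs) == 0) {
    message("repeatability not evaluable: no individual with consecutive years")
    return(tibble::tibble(mean_circ_diff = NA_real_, sd_circ_diff = NA_real_,
                          n_pairs = 0L, n_individuals = 0L))
  }
  d <- circular_diff_deg(pairs$value1, pairs$value2)
  tibble::tibble(mean_circ_diff = mean(d),
                 sd_circ_diff = if (length(d) > 1) sd(d) else NA_real_,
                 n_pairs = length(d),
                 n_individuals = dplyr::n_distinct(pairs$individual_id))
}

consecutive_pairs <- function(records) {
  stopifnot(all(c("individual_id", "year", "value") %in% names(records)))
  records |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::arrange(.data$individual_id, .data$year) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::reframe(
      year1 = .data$year[-dplyr::n()], year2 = .data$year[-1],
      value1 = .data$value[-dplyr::n()], value2 = .data$value[-1]
    ) |>
    dplyr::filter(.data$year2 - .data$year1 == 1)
}

#' First-year timing against subsequent years
#'
#' Mixed model of each subsequent-year value on the individual's first-year
#' value (random intercept per individual), quantifying whether early-career
#' timing predicts later timing; the report also frames the fitted slope
#' against the 1:1 line of perfect repeatability.
#'
#' @param records Tibble with `individual_id`, `year`, `value`.
#' @param min_individuals Minimum number of multi-year individuals.
#' @return A one-row tibble: `slope`, `std_error`, `t_value`, `p_value`,
#'   `slope_minus_one`, `n_pairs`, `n_individuals`, `fallback`. All-`NA`
#'   with a message when underpowered.
#' @export
first_vs_subsequent <- function(records, min_individuals = 5) {
  multi <- records |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::arrange(.data$individual_id, .data$year) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::mutate(first_value = dplyr::first(.data$value)) |>
    dplyr::slice(-1) |>
    dplyr::ungroup()
  n_ind <- dplyr::n_distinct(multi$individual_id)
  if (n_ind < min_individuals) {
    message("first-vs-subsequent not evaluable: only ", n_ind,
            " multi-year individuals")
    return(tibble::tibble(slope = NA_real_, std_error = NA_real_,
                          t_value = NA_real_, p_value = NA_real_,
                          slope_minus_one = NA_real_, n_pairs = nrow(multi),
                          n_individuals = n_ind, fallback = NA))
  }
  fit <- fit_random_intercept(value ~ first_value, multi)
  co <- fit$coefficients["first_value", ]
  tibble::tibble(slope = co[["Estimate"]], std_error = co[["Std. Error"]],
                 t_value = co[["t"]],
                 p_value = 2 * pt(-abs(co[["t"]]), df = nrow(multi) - 1),
                 slope_minus_one = co[["Estimate"]] - 1,
                 n_pairs = nrow(multi), n_individuals = n_ind,
                 fallback = fit$fallback)
}
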