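#' Flight speed / altitude response to the tailwind component
#'
#' Mixed model of a per-event flight response (corridor mean ground speed or
#' mean altitude) on the per-event tailwind component, with a random
#' intercept per individual. With fewer than `min_events` paired
#' observations, or a TWC series without contrast (constant), the response
#' is not evaluable and an all-`NA` report is returned with a message.
#'
#' @param data Tibble with one row per event: `individual_id`, `twc` (m/s)
#'   and the response column.
#' @param response Name of the response column (e.g. `"mean_speed"`).
#' @param min_events Minimum number of complete events.
#' @return A one-row tibble: `response`, `slope`, `std_error`, `t_value`,
#'   `p_value`, `n`, `fallback` (TRUE when the random intercept was singular
#'   and a fixed-effects fit was used).
#' @export
flight_response <- function(data, response, min_events = 5) {
  stopifnot(response %in% names(data), "twc" %in% names(data))
  d <- data[complete.cases(data[, c("individual_id", "twc", response)]), ]
  not_eval <- tibble::tibble(response = response, slope = NA_real_,
                             std_error = NA_real_, t_value = NA_real_,
                             p_value = NA_real_, n = nrow(d), fallback = NA)
  if (nrow(d) < min_events) {
    message("flight response '", response, "' not evaluable: only ",
            nrow(d), " events")
    return(not_eval)
  }
  if (var(d$twc) == 0) {
    message("flight response '", response, "' not evaluable: ",
            "no contrast in TWC")
    return(not_eval)
  }
  d$.y <- d[[response]]
  fit <- fit_random_intercept(.y ~ twc, d)
  co <- fit$coefficients["twc", ]
  tibble::tibble(response = response, slope = co[["Estimate"]],
                 std_error = co[["Std. Error"]],
                 t_value = co[["t"]],
                 p_value = 2 * pt(-abs(co[["t"]]), df = nrow(d) - 1),
                 n = nrow(d), fallback = fit$fallback)
}

#' Compare migration metrics between departures and arrivals
#'
#' For each metric, fits a mixed model of the metric on an event-kind
#' indicator (arrival vs departure) with a random intercept per individual,
#' reporting the arrival-minus-departure estimate, its standard error, Wald
#' t and p-value. Metrics observed for only one kind are marked not
#' evaluable.
#'
#' @param data Long tibble: `individual_id`, `kind`
#'   ("departure"/"arrival"), `metric`, `value`.
#' @return A tibble with one row per metric.
#' @export
compare_departure_arrival <- function(data) {
  stopifnot(all(c("individual_id", "kind", "metric", "value") %in% names(data)))
  data |>
    dplyr::group_by(.data$metric) |>
    dplyr::group_map(function(g, key) {
      g <- g[complete.cases(g[, c("individual_id", "kind", "value")]), ]
      base <- tibble::tibble(metric = key$metric, estimate = NA_real_,
                             std_error = NA_real_, t_value = NA_real_,
                             p_value = NA_real_,
                             n_departure = sum(g$kind == "departure"),
                             n_arrival = sum(g$kind == "arrival"))
      if (length(unique(g$kind)) < 2 || nrow(g) < 4 || var(g$value) == 0) {
        return(base)
      }
      g$.arrival <- as.numeric(g$kind == "arrival")
      fit <- fit_random_intercept(value ~ .arrival, g)
      co <- fit$coefficients[".arrival", ]
      base$estimate <- co[["Estimate"]]
      base$std_error <- co[["Std. Error"]]
      base$t_value <- co[["t"]]
      base$p_value <- 2 * pt(-abs(co[["t"]]), df = nrow(g) - 1)
      base
    }) |>
    dplyr::bind_rows()
}

# Random-intercept fit with fixed-effects fallback on singularity; returns
# the coefficient matrix with columns Estimate / Std. Error / t.
fit_random_intercept <- function(formula, data) {
  f <- stats::update(formula, . ~ . + (1 | individual_id))
  fallback <- FALSE
  model <- tryCatch({
    m <- suppressMessages(lme4::lmer(
      f, data = data,
      control = lme4::lmerControl(check.conv.singular =
                                    lme4::.makeCC("ignore", 1e-4))))
    if (lme4::isSingular(m, tol = 1e-4)) {
      fallback <- TRUE
      lm(formula, data = data)
    } else m
  }, error = function(e) {
    fallback <<- TRUE
    lm(formula, data = data)
  })
  co <- tryCatch(summary(model)$coefficients[, 1:2, drop = FALSE],
                 error = function(e) NULL)
  if (is.null(co)) {
    # degenerate mixed fits (e.g. zero residual variance) can fail only at
    # the summary stage; refit as fixed effects
    fallback <- TRUE
    model <- lm(formula, data = data)
    co <- summary(model)$coefficients[, 1:2, drop = FALSE]
  }
  colnames(co) <- c("Estimate", "Std. Error")
  co <- cbind(co, t = co[, "Estimate"] / co[, "Std. Error"])
  list(coefficients = co, model = model, fallback = fallback)
}
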