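#' Assemble the 38-column predictor matrix for departure/arrival modelling
#'
#' One row per migration event; 38 predictors: 24 weather contrasts (8 local
#' variables x {previous day, 4-year}, 4 large-scale variables x the same
#' two references), 2 tailwind-component contrasts, and 12 constant
#' bird/track predictors (number of migrations, sex, catching location,
#' year, time of day, breeding latitude, linear distance to the breeding
#' area, departure direction, time to first stop-over, duration of the first
#' stop-over, flown and linear distance to the first stop). Rows with any
#' missing predictor are dropped (and counted in the `dropped` attribute);
#' columns with more than two distinct values are standardised to mean 0,
#' SD 1, while 0/1 dummies are left as is. The outcome (`day_of_year`) is
#' untransformed.
#'
#' @param events Events tibble (one row per event; `individual_id`, `year`,
#'   `kind`, `day_of_year`, `time_of_day`, `mean_direction`).
#' @param contrasts Long contrasts tibble with `individual_id`, `year`,
#'   `variable`, `condition`, `value` (e.g. [build_contrasts()] output bound
#'   over events with event keys added).
#' @param track_metrics Tibble keyed by `individual_id`, `year` with the
#'   first-stop/track columns from [track_metrics()].
#' @param roster Tibble with `individual_id`, `sex`, `catching_location`.
#' @return A tibble of class `predictor_matrix`: key columns
#'   (`individual_id`, `year`), outcome `day_of_year`, and the 38 predictor
#'   columns (attribute `predictors` holds their names, `dropped` the count
#'   of incomplete rows removed, `scaling` the centring/scaling constants).
#' @export
build_matrix <- function(events, contrasts, track_metrics, roster) {
  wide <- contrasts |>
    dplyr::mutate(col = ifelse(.data$variable == "twc",
                               paste0("twc_", sub("_local$", "", .data$condition)),
                               paste(.data$condition, .data$variable, sep = "_"))) |>
    dplyr::select("individual_id", "year", "col", "value") |>
    tidyr::pivot_wider(names_from = "col", values_from = "value")

  df <- events |>
    dplyr::left_join(wide, by = c("individual_id", "year")) |>
    dplyr::left_join(track_metrics, by = c("individual_id", "year")) |>
    dplyr::left_join(roster[, c("individual_id", "sex", "catching_location")],
                     by = "individual_id") |>
    dplyr::arrange(.data$individual_id, .data$year) |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::mutate(n_migrations = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      sex_male = as.numeric(.data$sex == "M"),
      catching_loc = as.numeric(.data$catching_location ==
                                  sort(unique(.data$catching_location))[1]),
      time_of_day_h = parse_hhmm(.data$time_of_day),
      departure_direction = .data$mean_direction
    )

  pred_cols <- c(
    contrast_col_names(),
    "twc_prev_day", "twc_four_year",
    "n_migrations", "sex_male", "catching_loc", "year", "time_of_day_h",
    "breeding_lat", "linear_distance_km", "departure_direction",
    "flight_time_h", "first_stop_duration_d",
    "flown_to_first_stop_km", "linear_to_first_stop_km"
  )
  missing <- setdiff(pred_cols, names(df))
  if (length(missing)) {
    stop("cannot assemble predictor matrix; missing inputs for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  keep <- complete.cases(df[, c("day_of_year", pred_cols)])
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(dropped, " event(s) dropped for missing predictors")
  }
  df <- df[keep, c("individual_id", "year", "kind"[("kind" %in% names(df))],
                   "day_of_year", pred_cols)]
  if (nrow(df) < 10) {
    stop("only ", nrow(df), " complete events; at least 10 are required ",
         "to fit the driver models", call. = FALSE)
  }

  scaling <- list()
  for (p in pred_cols) {
    x <- df[[p]]
    if (length(unique(x)) > 2) {
      s <- sd(x)
      if (s == 0) s <- 1
      scaling[[p]] <- c(center = mean(x), scale = s)
      df[[p]] <- (x - mean(x)) / s
    }
  }
  structure(df, class = c("predictor_matrix", class(df)),
            predictors = pred_cols, dropped = dropped, scaling = scaling)
}

contrast_col_names <- function() {
  c(as.vector(outer(c("prev_day_local", "four_year_local"),
                    local_weather_vars(), paste, sep = "_")),
    as.vector(outer(c("prev_day_large", "four_year_large"),
                    large_weather_vars(), paste, sep = "_")))
}

parse_hhmm <- function(x) {
  if (is.numeric(x)) return(x)
  h <- as.numeric(substr(x, 1, 2))
  m <- as.numeric(substr(x, 4, 5))
  h + m / 60
}

#' LASSO screen of the predictor matrix
#'
#' L1-penalised linear regression of day-of-year on all predictors, with the
#' penalty chosen by k-fold cross-validation at the one-standard-error rule;
#' predictors with non-zero coefficients at that penalty are the selected
#' set. Folds are assigned at the individual level (all events of a bird
#' share a fold) so the cross-validation respects the repeated-measures
#' grouping; the assignment is deterministic given `seed`.
#'
#' @param pm A `predictor_matrix` from [build_matrix()].
#' @param k_folds Number of CV folds (>= 3).
#' @param seed Integer seed controlling the fold assignment.
#' @param rule `"lambda.1se"` (default) or `"lambda.min"`.
#' @return An object of class `lasso_screen`: list with `selected`
#'   (character), `lambda`, `cv` (tibble of the CV curve) and `fit`.
#' @export
lasso_screen <- function(pm, k_folds = 5, seed = 1, rule = "lambda.1se") {
  stopifnot(inherits(pm, "predictor_matrix"), k_folds >= 3)
  preds <- attr(pm, "predictors")
  y <- pm$day_of_year
  if (var(y) == 0) stop("outcome has zero variance", call. = FALSE)
  x <- as.matrix(pm[, preds])

  ids <- unique(pm$individual_id)
  foldid <- withr::with_seed(as.integer(seed), {
    id_fold <- setNames(rep_len(sample(k_folds), length(ids)), sample(ids))
    # reshuffle so fold sizes are balanced over a random individual order
    unname(id_fold[pm$individual_id])
  })
  cvfit <- glmnet::cv.glmnet(x, y, foldid = foldid, standardize = FALSE,
                             alpha = 1)
  lambda <- cvfit[[rule]]
  beta <- as.matrix(coef(cvfit, s = lambda))
  selected <- rownames(beta)[beta[, 1] != 0]
  selected <- setdiff(selected, "(Intercept)")
  structure(list(selected = selected, lambda = lambda, rule = rule,
                 cv = tibble::tibble(lambda = cvfit$lambda,
                                     cvm = cvfit$cvm, cvsd = cvfit$cvsd,
                                     nzero = as.integer(cvfit$nzero)),
                 fit = cvfit, k_folds = k_folds, seed = seed),
            class = "lasso_screen")
}

#' @export
print.lasso_screen <- function(x, ...) {
  cat("LASSO screen (", x$k_folds, "-fold CV, ", x$rule, ")\n", sep = "")
  cat("lambda =", signif(x$lambda, 4), "\n")
  if (length(x$selected)) {
    cat("selected:", paste(x$selected, collapse = ", "), "\n")
  } else {
    cat("no predictors selected\n")
  }
  invisible(x)
}

#' Confirmatory mixed model on the selected predictors
#'
#' Refits the screened predictors jointly in a linear mixed model of
#' day-of-year with a random intercept per individual (guarding against
#' pseudo-replication from repeated migrations of the same bird). Wald t
#' statistics with an n-1 degrees-of-freedom approximation give per-term
#' p-values; a predictor is flagged significant only below the
#' alpha-inflation-corrected threshold (default 0.01). A singular random
#' intercept falls back to the fixed-effects-only fit with a warning. For
#' count-like outcomes, [select_outcome_family()] compares candidate
#' distributions by AIC; day-of-year is treated as Gaussian by default.
#'
#' @param pm A `predictor_matrix`.
#' @param selected Character vector of predictor names (e.g. from
#'   [lasso_screen()]). An empty selection is a valid outcome and returns an
#'   empty coefficient table.
#' @param alpha Significance threshold after alpha correction.
#' @param compare_families Also run the AIC distribution comparison (only
#'   meaningful for count-like outcomes; requires glmmTMB).
#' @return An object of class `driver_fit` with a coefficient tibble
#'   (`term`, `estimate`, `std_error`, `t_value`, `p_value`, `significant`),
#'   the fitted model, the distribution used, and bookkeeping fields.
#' @export
confirm_glmm <- function(pm, selected, alpha = 0.01, compare_families = FALSE) {
  stopifnot(inherits(pm, "predictor_matrix"))
  n <- nrow(pm)
  family <- "gaussian"
  if (compare_families) {
    fam <- select_outcome_family(pm$day_of_year, pm, selected)
    family <- fam$family
  }
  if (length(selected) == 0) {
    return(structure(list(
      coefficients = tibble::tibble(term = character(), estimate = numeric(),
                                    std_error = numeric(), t_value = numeric(),
                                    p_value = numeric(), significant = logical()),
      selected = character(), model = NULL, fallback = FALSE,
      alpha = alpha, family = family, n = n,
      note = "no predictors selected"), class = "driver_fit"))
  }
  f <- stats::as.formula(paste(
    "day_of_year ~", paste(selected, collapse = " + "), "+ (1 | individual_id)"))
  fallback <- FALSE
  model <- tryCatch({
    m <- lme4::lmer(f, data = pm, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  lme4::.makeCC("ignore", 1e-4)))
    if (lme4::isSingular(m, tol = 1e-4)) {
      fallback <- TRUE
      warning("singular random-intercept fit; falling back to ",
              "fixed-effects-only model", call. = FALSE)
      lm(stats::as.formula(paste("day_of_year ~",
                                 paste(selected, collapse = " + "))), data = pm)
    } else m
  }, error = function(e) {
    fallback <<- TRUE
    warning("mixed-model fit failed (", conditionMessage(e),
            "); falling back to fixed-effects-only model", call. = FALSE)
    lm(stats::as.formula(paste("day_of_year ~",
                               paste(selected, collapse = " + "))), data = pm)
  })
  co <- if (inherits(model, "merMod")) {
    summary(model)$coefficients
  } else {
    summary(model)$coefficients[, 1:3, drop = FALSE]
  }
  tv <- co[, "Estimate"] / co[, "Std. Error"]
  pv <- 2 * pt(-abs(tv), df = n - 1)
  coefs <- tibble::tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    std_error = unname(co[, "Std. Error"]),
    t_value = unname(tv),
    p_value = unname(pv),
    significant = unname(pv < alpha)
  ) |> dplyr::filter(.data$term != "(Intercept)")
  structure(list(coefficients = coefs, selected = selected, model = model,
                 fallback = fallback, alpha = alpha, family = family, n = n,
                 note = NULL),
            class = "driver_fit")
}

#' @export
print.driver_fit <- function(x, ...) {
  cat("Confirmatory mixed model (n = ", x$n, ", random intercept per ",
      "individual", if (x$fallback) "; FELL BACK to fixed effects", ")\n",
      sep = "")
  if (!is.null(x$note)) cat(x$note, "\n")
  if (nrow(x$coefficients)) {
    print(as.data.frame(x$coefficients), digits = 3)
    cat("significance threshold: p <", x$alpha, "\n")
  }
  invisible(x)
}

#' Choose an outcome distribution by AIC
#'
#' Compares Poisson, negative-binomial and Tweedie mixed models (random
#' intercept per individual) of a count-like outcome by AIC. Non-count
#' outcomes short-circuit to Gaussian.
#'
#' @param y Outcome vector.
#' @param pm `predictor_matrix` holding the grouping and predictors.
#' @param selected Predictors to include.
#' @return List with `family` (name) and `aic` (named vector, NA for
#'   families that failed to fit).
#' @export
select_outcome_family <- function(y, pm, selected) {
  county <- all(y >= 0) && all(abs(y - round(y)) < 1e-8)
  if (!county || !requireNamespace("glmmTMB", quietly = TRUE)) {
    return(list(family = "gaussian", aic = c(gaussian = NA_real_)))
  }
  rhs <- if (length(selected)) paste(selected, collapse = " + ") else "1"
  f <- stats::as.formula(paste("day_of_year ~", rhs, "+ (1 | individual_id)"))
  fams <- list(poisson = stats::poisson(),
               nbinom = glmmTMB::nbinom2(),
               tweedie = glmmTMB::tweedie())
  aic <- purrr::map_dbl(fams, function(fam) {
    tryCatch(AIC(glmmTMB::glmmTMB(f, data = pm, family = fam)),
             error = function(e) NA_real_, warning = function(w) NA_real_)
  })
  if (all(is.na(aic))) return(list(family = "gaussian", aic = aic))
  list(family = names(which.min(aic)), aic = aic)
}

#' One-call driver screen: LASSO then confirmatory mixed model
#'
#' @inheritParams lasso_screen
#' @inheritParams confirm_glmm
#' @return A `driver_fit` whose `screen` element holds the
#'   [lasso_screen()] result.
#' @export
screen_drivers <- function(pm, k_folds = 5, seed = 1, alpha = 0.01) {
  sc <- lasso_screen(pm, k_folds = k_folds, seed = seed)
  fit <- confirm_glmm(pm, sc$selected, alpha = alpha)
  fit$screen <- sc
  fit
}
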