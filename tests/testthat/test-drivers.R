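sim_pm <- function(seed, n_events = 42) {
  cfg <- sim_config(seed = seed)
  sim <- simulate_driver_events(cfg, n_events = n_events)
  suppressMessages(build_matrix(sim$events, sim$contrasts, sim$track_metrics,
                                sim$roster))
}

test_that("the predictor matrix has 38 standardized columns", {
  pm <- sim_pm(31, n_events = 42)
  preds <- attr(pm, "predictors")
  expect_length(preds, 38)
  expect_equal(nrow(pm), 42)
  cont <- preds[vapply(preds, function(p) length(unique(pm[[p]])) > 2,
                       logical(1))]
  for (p in cont) {
    expect_lt(abs(mean(pm[[p]])), 1e-10)
    expect_equal(sd(pm[[p]]), 1, tolerance = 1e-10)
  }
})

test_that("rows with missing predictors are dropped and counted", {
  cfg <- sim_config(seed = 32)
  sim <- simulate_driver_events(cfg, n_events = 42)
  sim$contrasts$value[1] <- NA  # one event loses one contrast
  expect_message(
    pm <- build_matrix(sim$events, sim$contrasts, sim$track_metrics,
                       sim$roster),
    "1 event")
  expect_equal(nrow(pm), 41)
  expect_equal(attr(pm, "dropped"), 1)
})

test_that("an underdetermined matrix is refused", {
  cfg <- sim_config(seed = 33)
  sim <- simulate_driver_events(cfg, n_events = 12)
  sim$contrasts$value[sim$contrasts$individual_id %in%
                        paste0("C0", 1:4)] <- NA
  expect_error(
    suppressMessages(build_matrix(sim$events, sim$contrasts,
                                  sim$track_metrics, sim$roster)),
    "at least 10")
})

test_that("the LASSO screen is deterministic and order-invariant", {
  pm <- sim_pm(34, n_events = 60)
  s1 <- lasso_screen(pm, seed = 9)
  s2 <- lasso_screen(pm, seed = 9)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$lambda, s2$lambda)
  # permute predictor columns: same selected set
  preds <- attr(pm, "predictors")
  perm <- rev(preds)
  pm2 <- pm[, c("individual_id", "year", "kind", "day_of_year", perm)]
  attr(pm2, "predictors") <- perm
  class(pm2) <- class(pm)
  s3 <- lasso_screen(pm2, seed = 9)
  expect_setequal(s3$selected, s1$selected)
  f1 <- confirm_glmm(pm, s1$selected)
  f3 <- confirm_glmm(pm2, s3$selected)
  expect_equal(
    f1$coefficients$estimate[order(f1$coefficients$term)],
    f3$coefficients$estimate[order(f3$coefficients$term)],
    tolerance = 1e-8)
})

test_that("at most one of a perfectly collinear pair is selected", {
  pm <- sim_pm(35, n_events = 60)
  pm$prev_day_local_temperature <- pm$linear_distance_km  # duplicate planted
  sc <- lasso_screen(pm, seed = 2)
  expect_lt(sum(c("prev_day_local_temperature", "linear_distance_km") %in%
                  sc$selected), 2)
})

test_that("the penalized path approaches least squares as penalty vanishes", {
  pm <- sim_pm(36, n_events = 70)
  preds <- attr(pm, "predictors")
  x <- as.matrix(pm[, preds])
  g <- glmnet::glmnet(x, pm$day_of_year, alpha = 1, standardize = FALSE,
                      lambda = c(1, 0.1, 0.01, 1e-4, 0), thresh = 1e-13)
  b_lasso <- as.numeric(coef(g, s = 0))
  b_ols <- coef(lm(pm$day_of_year ~ x))
  expect_lt(max(abs(b_lasso - unname(b_ols)), na.rm = TRUE), 1e-3)
})

test_that("zero-variance outcomes are refused", {
  pm <- sim_pm(37, n_events = 40)
  pm$day_of_year <- 108
  expect_error(lasso_screen(pm), "zero variance")
})

test_that("the confirmatory model recovers a planted slope", {
  cfg <- sim_config(seed = 38)
  sim <- simulate_driver_events(cfg, n_events = 80)
  pm <- suppressMessages(build_matrix(sim$events, sim$contrasts,
                                      sim$track_metrics, sim$roster))
  fit <- confirm_glmm(pm, c("linear_distance_km", "breeding_lat"))
  co <- fit$coefficients
  # planted slope on the standardized scale: beta * SD of the raw predictor
  raw_sd <- attr(pm, "scaling")[["linear_distance_km"]][["scale"]]
  planted <- cfg$beta_distance * raw_sd
  est <- co$estimate[co$term == "linear_distance_km"]
  se <- co$std_error[co$term == "linear_distance_km"]
  expect_lt(abs(est - planted), 2.5 * se)
  expect_true(all(co$significant))
})

test_that("one observation per individual degenerates to least squares", {
  cfg <- sim_config(seed = 39, n_individuals = 40, years = 2017)
  sim <- simulate_driver_events(cfg, n_events = 40)
  pm <- suppressMessages(build_matrix(sim$events, sim$contrasts,
                                      sim$track_metrics, sim$roster))
  expect_warning(fit <- confirm_glmm(pm, c("linear_distance_km",
                                           "breeding_lat")),
                 "singular|falling back")
  ols <- lm(day_of_year ~ linear_distance_km + breeding_lat, data = pm)
  expect_equal(fit$coefficients$estimate,
               unname(coef(ols)[c("linear_distance_km", "breeding_lat")]),
               tolerance = 1e-6)
})

test_that("an empty selection is a valid outcome", {
  pm <- sim_pm(40, n_events = 40)
  fit <- confirm_glmm(pm, character())
  expect_equal(nrow(fit$coefficients), 0)
  expect_match(fit$note, "no predictors")
  expect_equal(nrow(tidy(fit)), 0)
  expect_equal(glance(fit)$n_selected, 0)
})

test_that("flight responses recover a planted wind-support slope", {
  set.seed(41)
  n <- 40
  d <- tibble::tibble(
    individual_id = rep(sprintf("C%02d", 1:20), 2),
    twc = rnorm(n, 0, 3),
    mean_speed = 65 + 3.6 * rnorm(n, 0, 3) * 0 + NA
  )
  b_i <- rnorm(20, 0, 3)[rep(1:20, 2)]
  d$mean_speed <- 65 + 3.6 * d$twc + b_i + rnorm(n, 0, 2)
  fr <- flight_response(d, "mean_speed")
  expect_lt(abs(fr$slope - 3.6) / 3.6, 0.15)
  expect_lt(fr$p_value, 0.001)
  # constant TWC: not evaluable
  d2 <- d; d2$twc <- 1
  expect_message(fr2 <- flight_response(d2, "mean_speed"), "no contrast")
  expect_true(is.na(fr2$slope))
  expect_message(fr3 <- flight_response(d[1:3, ], "mean_speed"), "only 3")
  expect_true(is.na(fr3$slope))
})

test_that("departure-arrival comparisons find planted contrasts", {
  set.seed(42)
  n_ind <- 15
  mk <- function(kind, alt_mean) tibble::tibble(
    individual_id = sprintf("C%02d", 1:n_ind), kind = kind,
    metric = "mean_altitude",
    value = alt_mean + rnorm(n_ind, 0, 150))
  d <- dplyr::bind_rows(mk("departure", 1100), mk("arrival", 200))
  cmp <- compare_departure_arrival(d)
  expect_lt(cmp$estimate, 0)   # arrivals lower, planted direction
  expect_lt(cmp$p_value, 0.001)
  # a metric present for only one kind is not evaluable
  d2 <- d; d2$value[d2$kind == "arrival"] <- NA
  cmp2 <- compare_departure_arrival(d2)
  expect_true(is.na(cmp2$estimate))
  # single individual providing both kinds still fits
  d3 <- dplyr::bind_rows(mk("departure", 1100), mk("arrival", 200))
  d3$individual_id <- "C01"
  expect_s3_class(compare_departure_arrival(d3), "tbl_df")
})

test_that("family selection short-circuits to gaussian for non-counts", {
  pm <- sim_pm(43, n_events = 40)
  fam <- select_outcome_family(pm$day_of_year, pm, "linear_distance_km")
  expect_equal(fam$family, "gaussian")
  skip_if_not_installed("glmmTMB")
  pm$day_of_year <- round(pm$day_of_year)
  fam2 <- select_outcome_family(pm$day_of_year, pm, "linear_distance_km")
  expect_true(fam2$family %in% c("poisson", "nbinom", "tweedie", "gaussian"))
})
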