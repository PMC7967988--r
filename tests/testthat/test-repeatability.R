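rec <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) tibble::tibble(
    individual_id = r[[1]], year = r[[2]], value = r[[3]])))
}

test_that("mean absolute difference matches hand-computed toy values", {
  r1 <- rec(list("A", 2015:2017, c(100, 100, 100)))
  m1 <- mean_abs_diff(r1)
  expect_equal(m1$mean_abs_diff, 0)
  expect_equal(m1$n_pairs, 2L)

  r2 <- rec(list("A", 2015:2016, c(100, 104)))
  m2 <- mean_abs_diff(r2)
  expect_equal(m2$mean_abs_diff, 4)
  expect_equal(m2$n_pairs, 1L)

  r3 <- rec(list("A", 2015:2016, c(100, 103)),
            list("B", 2015:2016, c(110, 111)))
  m3 <- mean_abs_diff(r3)
  expect_equal(m3$mean_abs_diff, 2)
  expect_equal(m3$sd_abs_diff, sd(c(3, 1)))
  expect_equal(m3$n_pairs, 2L)
  expect_equal(m3$n_individuals, 2L)
})

test_that("pairs are consecutive-year only and translation-invariant", {
  gap <- rec(list("A", c(2015, 2017), c(100, 120)))  # missing middle year
  expect_message(mg <- mean_abs_diff(gap), "not evaluable")
  expect_equal(mg$n_pairs, 0L)

  set.seed(5)
  r <- rec(list("A", 2014:2018, round(runif(5, 95, 125))),
           list("B", 2015:2017, round(runif(3, 95, 125))))
  m <- mean_abs_diff(r)
  shifted <- r; shifted$value <- shifted$value + 17
  expect_equal(mean_abs_diff(shifted)$mean_abs_diff, m$mean_abs_diff)
  # symmetric in year order within pairs
  rev_r <- r; rev_r$value <- -rev_r$value
  expect_equal(mean_abs_diff(rev_r)$mean_abs_diff, m$mean_abs_diff)
})

test_that("the z-score variant runs and is scale-free", {
  r <- rec(list("A", 2015:2017, c(100, 104, 102)),
           list("B", 2015:2017, c(120, 112, 116)))
  mz <- mean_abs_diff(r, standardize = "zscore")
  r2 <- r; r2$value <- r$value * 3 + 5
  expect_equal(mean_abs_diff(r2, standardize = "zscore")$mean_abs_diff,
               mz$mean_abs_diff)
})

test_that("direction repeatability uses the shortest arc", {
  expect_equal(direction_repeatability(
    rec(list("A", 2015:2016, c(359, 1))))$mean_circ_diff, 2)
  expect_equal(direction_repeatability(
    rec(list("A", 2015:2016, c(45, 45))))$mean_circ_diff, 0)
  expect_equal(direction_repeatability(
    rec(list("A", 2015:2016, c(0, 180))))$mean_circ_diff, 180)
  set.seed(6)
  r <- rec(list("A", 2014:2018, runif(5, 0, 360)))
  d <- direction_repeatability(r)
  expect_true(d$mean_circ_diff >= 0 && d$mean_circ_diff <= 180)
})

test_that("first-year timing predicts subsequent years when planted", {
  # perfectly repeatable birds: identity slope
  ids <- sprintf("C%02d", 1:8)
  perf <- tibble::tibble(individual_id = rep(ids, each = 3),
                         year = rep(2015:2017, 8),
                         value = rep(100 + seq(0, 28, by = 4), each = 3))
  f <- suppressWarnings(first_vs_subsequent(perf))
  expect_equal(f$slope, 1, tolerance = 1e-6)
  expect_equal(f$slope_minus_one, 0, tolerance = 1e-6)

  # planted individual signal: slope significantly positive
  set.seed(7)
  b <- rnorm(12, 0, 3)
  planted <- tibble::tibble(individual_id = rep(sprintf("C%02d", 1:12), each = 3),
                            year = rep(2015:2017, 12),
                            value = 108 + rep(b, each = 3) + rnorm(36, 0, 2))
  fp <- first_vs_subsequent(planted)
  expect_gt(fp$slope, 0)
  expect_lt(fp$p_value, 0.01)

  # underpowered input is not evaluable
  expect_message(fu <- first_vs_subsequent(planted[1:6, ]), "not evaluable")
  expect_true(is.na(fu$slope))
})

test_that("values shuffled across individuals show no first-year signal", {
  set.seed(8)
  cover <- 0
  for (i in 1:25) {
    vals <- sample(100:130, 36, replace = TRUE)
    null <- tibble::tibble(individual_id = rep(sprintf("C%02d", 1:12), each = 3),
                           year = rep(2015:2017, 12), value = vals)
    f <- suppressWarnings(first_vs_subsequent(null))
    ci <- f$slope + c(-1, 1) * 1.96 * f$std_error
    if (ci[1] <= 0 && ci[2] >= 0) cover <- cover + 1
  }
  expect_gte(cover / 25, 0.8)
})
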