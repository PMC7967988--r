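#' Tidy a confirmatory driver fit
#'
#' @param x A `driver_fit` from [confirm_glmm()] or [screen_drivers()].
#' @param ... Unused.
#' @return A tibble with one row per fitted term: `term`, `estimate`,
#'   `std_error`, `t_value`, `p_value`, `significant`.
#' @export
tidy.driver_fit <- function(x, ...) {
  x$coefficients
}

#' One-row summary of a driver fit
#'
#' @param x A `driver_fit`.
#' @param ... Unused.
#' @return A tibble: `n`, `n_selected`, `n_significant`, `alpha`, `family`,
#'   `fallback`.
#' @export
glance.driver_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_selected = length(x$selected),
                 n_significant = sum(x$coefficients$significant),
                 alpha = x$alpha, family = x$family, fallback = x$fallback)
}

#' Tidy a LASSO screen
#'
#' @param x A `lasso_screen`.
#' @param ... Unused.
#' @return The cross-validation curve as a tibble (`lambda`, `cvm`, `cvsd`,
#'   `nzero`) with an added `selected_at_rule` flag on the chosen lambda.
#' @export
tidy.lasso_screen <- function(x, ...) {
  dplyr::mutate(x$cv, selected_at_rule = .data$lambda == x$lambda)
}

#' One-row summary of a LASSO screen
#'
#' @param x A `lasso_screen`.
#' @param ... Unused.
#' @return A tibble: `lambda`, `rule`, `k_folds`, `n_selected`.
#' @export
glance.lasso_screen <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, rule = x$rule, k_folds = x$k_folds,
                 n_selected = length(x$selected))
}
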