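#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a reverse regression fit
#'
#' @param x An `erk_regression`.
#' @param scale `"standardized"` (z-scored predictors) or `"raw"`.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`.
#' @export
tidy.erk_regression <- function(x, scale = c("standardized", "raw"), ...) {
  scale <- match.arg(scale)
  b <- if (scale == "standardized") x$coefficients else x$coefficients_raw
  tibble::tibble(term = names(b), estimate = unname(b))
}

#' @rdname tidy.erk_regression
#' @export
glance.erk_regression <- function(x, ...) {
  tibble::tibble(feature = x$feature, r_squared = x$r2, rmse = x$rmse,
                 n = x$n, n_predictors = length(x$predictors),
                 best_fold = x$best_fold)
}

#' Tidy a biosensor calibration
#'
#' @param x A `fret_calibration`.
#' @param ... Unused.
#' @return Tibble with the two calibration endpoints.
#' @export
tidy.fret_calibration <- function(x, ...) {
  tibble::tibble(term = c("k_au", "k_ap"), estimate = c(x$k_au, x$k_ap))
}

#' @rdname tidy.fret_calibration
#' @export
glance.fret_calibration <- function(x, ...) {
  tibble::tibble(k_au = x$k_au, k_ap = x$k_ap, span = x$k_ap - x$k_au,
                 r_squared = if (!is.null(x$fit)) summary(x$fit)$r.squared
                             else NA_real_)
}

#' Tidy a forward model's cross-validated metrics
#'
#' @param x An `erk_forward` or `erk_cnn` model.
#' @param ... Unused.
#' @return The per-fold metrics tibble.
#' @export
tidy.erk_forward <- function(x, ...) x$metrics

#' @rdname tidy.erk_forward
#' @export
glance.erk_forward <- function(x, ...) {
  test <- dplyr::filter(x$metrics, .data$split == "test")
  tibble::tibble(model = class(x)[1], test_r2 = mean(test$r2),
                 test_mse = mean(test$mse), n_folds = nrow(test))
}

#' @rdname tidy.erk_forward
#' @export
tidy.erk_cnn <- function(x, ...) x$metrics

#' @rdname tidy.erk_forward
#' @export
glance.erk_cnn <- function(x, ...) {
  test <- dplyr::filter(x$metrics, .data$split == "test")
  tibble::tibble(model = "erk_cnn", test_r2 = mean(test$r2),
                 test_mse = mean(test$mse), n_folds = nrow(test))
}

#' Tidy a signaling-history classifier
#'
#' @param x An `erk_history_classifier`.
#' @param ... Unused.
#' @return Tibble of per-stain predictor importances.
#' @export
tidy.erk_history_classifier <- function(x, ...) {
  tibble::tibble(target = names(x$importance),
                 importance = unname(x$importance))
}

#' @rdname tidy.erk_history_classifier
#' @export
glance.erk_history_classifier <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, cv_accuracy = x$cv_accuracy,
                 n_classes = length(x$classes), n_test = x$n_test,
                 n_rounds = length(x$ensemble$trees))
}
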