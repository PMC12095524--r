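# Cross-validated linear regression engine shared by the reverse models.
# Stains enter on log10 scale and predictors are z-scored by default;
# coefficients are reported on both scales.
fit_reverse_engine <- function(X, y, folds, seed, feature, predictors) {
  ok <- complete.cases(X) & is.finite(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- nrow(X)
  abort_if(n < 2 * folds, "too few cells for the requested folds")
  abort_if(any(apply(X, 2, var) == 0), "zero-variance predictor")
  mu <- colMeans(X); sdev <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")

  fold_of <- with_seed(seed, rep_len(seq_len(folds), n)[sample.int(n)])
  cv <- purrr::map_dfr(seq_len(folds), function(f) {
    tr <- fold_of != f
    beta <- pinv_lsfit(Xs[tr, , drop = FALSE], y[tr])
    pred <- drop(cbind(1, Xs[!tr, , drop = FALSE]) %*% beta)
    tibble::tibble(fold = f, rmse_test = sqrt(mean((y[!tr] - pred)^2)))
  })
  # the paper's rule: keep the fold model with the lowest test RMSE, then
  # refit it on the full data and report that model's R^2
  beta_full <- pinv_lsfit(Xs, y)
  pred_full <- drop(cbind(1, Xs) %*% beta_full)
  raw_slopes <- beta_full[-1] / sdev
  raw_intercept <- beta_full[1] - sum(raw_slopes * mu)
  structure(list(
    feature = feature, predictors = predictors,
    coefficients = beta_full,
    coefficients_raw = c(`(Intercept)` = unname(raw_intercept), raw_slopes),
    cv = cv, best_fold = cv$fold[which.min(cv$rmse_test)],
    r2 = r_squared(y, pred_full),
    rmse = sqrt(mean((y - pred_full)^2)), n = n,
    scaling = list(mu = mu, sd = sdev)),
    class = "erk_regression")
}

#' @export
print.erk_regression <- function(x, ...) {
  cat("Reverse regression for `", x$feature, "`: ",
      length(x$predictors), " predictor(s); R2 = ", signif(x$r2, 3),
      " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @export
predict.erk_regression <- function(object, stains, log10_stains = TRUE, ...) {
  X <- as.matrix(stains[, object$predictors, drop = FALSE])
  if (log10_stains) X <- log10(X)
  drop(cbind(1, X) %*% object$coefficients_raw)
}

reverse_design <- function(stains, features, feature, predictors,
                           log10_stains) {
  abort_if(!feature %in% names(features),
           sprintf("unknown feature `%s`", feature))
  shared <- intersect(stains$cell_id, features$cell_id)
  abort_if(length(shared) < 50, "need at least 50 cells")
  X <- as.matrix(stains[match(shared, stains$cell_id), predictors,
                        drop = FALSE])
  if (log10_stains) X <- log10(X)
  y <- features[[feature]][match(shared, features$cell_id)]
  list(X = X, y = y)
}

#' Single-stain regression of an ERK dynamic feature
#'
#' 10-fold cross-validated simple linear regression predicting one dynamic
#' feature from one stain target (log10 intensity by default). The fold model
#' with the lowest test RMSE is selected and refit on the full data; the
#' reported R-squared is that final fit's.
#'
#' @param stains Wide stain table.
#' @param features Feature table from [erk_features()].
#' @param feature Feature name (see [erk_feature_names()]).
#' @param target Stain column to use as the predictor.
#' @param folds CV folds (default 10).
#' @param seed RNG seed.
#' @param log10_stains Regress on log10 stains (default `TRUE`).
#' @return `erk_regression` object.
#' @export
fit_reverse_single <- function(stains, features, feature, target, folds = 10,
                               seed = 1, log10_stains = TRUE) {
  d <- reverse_design(stains, features, feature, target, log10_stains)
  fit_reverse_engine(d$X, d$y, folds, seed, feature, target)
}

#' Multiple regression of an ERK dynamic feature on all stains
#'
#' As [fit_reverse_single()] with the full stain panel as predictors.
#'
#' @inheritParams fit_reverse_single
#' @param targets Predictor columns; default all stain targets.
#' @return `erk_regression` object.
#' @export
fit_reverse_mlr <- function(stains, features, feature, targets = NULL,
                            folds = 10, seed = 1, log10_stains = TRUE) {
  targets <- targets %||% stain_targets(stains)
  d <- reverse_design(stains, features, feature, targets, log10_stains)
  fit_reverse_engine(d$X, d$y, folds, seed, feature, targets)
}

#' Incremental predictor addition
#'
#' Ranks stains by their single-predictor R-squared for the feature, then
#' adds them to the model one at a time in rank order, reporting the
#' cumulative in-sample R-squared (non-decreasing by nesting; the endpoint
#' equals the full multiple regression's in-sample R-squared).
#'
#' @inheritParams fit_reverse_mlr
#' @return Tibble: `step`, `predictor`, `single_r2`, `cumulative_r2`.
#' @export
incremental_predictors <- function(stains, features, feature, targets = NULL,
                                   log10_stains = TRUE) {
  targets <- targets %||% stain_targets(stains)
  d <- reverse_design(stains, features, feature, targets, log10_stains)
  single <- vapply(seq_along(targets), function(j) {
    suppressWarnings(cor(d$X[, j], d$y)^2)
  }, numeric(1))
  ord <- order(single, decreasing = TRUE)
  cum <- vapply(seq_along(ord), function(m) {
    beta <- pinv_lsfit(d$X[, ord[seq_len(m)], drop = FALSE], d$y)
    r_squared(d$y, drop(cbind(1, d$X[, ord[seq_len(m)], drop = FALSE]) %*% beta))
  }, numeric(1))
  tibble::tibble(step = seq_along(ord), predictor = targets[ord],
                 single_r2 = single[ord], cumulative_r2 = cum)
}

#' Condition-average regression
#'
#' Averages stains (log10) and features over all cells sharing a condition,
#' then regresses the feature's condition means on the stain condition means.
#' Cell-level measurement noise averages out, so condition-level fits bound
#' the single-cell fits from above when noise is independent across cells.
#'
#' @inheritParams fit_reverse_mlr
#' @param cells Cell table mapping `cell_id` to `condition`.
#' @param targets Predictor columns; default all.
#' @return `erk_regression` object fitted on condition means (leave-one-out
#'   CV when fewer conditions than folds).
#' @export
condition_average_model <- function(stains, features, cells, feature,
                                    targets = NULL, folds = 10, seed = 1,
                                    log10_stains = TRUE) {
  targets <- targets %||% stain_targets(stains)
  d <- stains[, c("cell_id", targets)] |>
    dplyr::inner_join(features[, c("cell_id", feature)], by = "cell_id") |>
    dplyr::inner_join(cells[, c("cell_id", "condition")], by = "cell_id")
  n_cond <- length(unique(d$condition))
  abort_if(n_cond < 3, "need at least 3 conditions")
  if (n_cond < 5) warning("fewer than 5 conditions; fit is fragile")
  avg <- d |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(targets),
                    ~ if (log10_stains) mean(log10(.x)) else mean(.x)),
      dplyr::across(dplyr::all_of(feature), mean), .groups = "drop")
  X <- as.matrix(avg[, targets, drop = FALSE])
  y <- avg[[feature]]
  n <- nrow(X)
  folds <- min(folds, n)
  mu <- colMeans(X); sdev <- apply(X, 2, sd)
  abort_if(any(sdev == 0), "zero-variance predictor across conditions")
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  fold_of <- with_seed(seed, rep_len(seq_len(folds), n)[sample.int(n)])
  cv <- purrr::map_dfr(seq_len(folds), function(f) {
    tr <- fold_of != f
    beta <- pinv_lsfit(Xs[tr, , drop = FALSE], y[tr])
    pred <- drop(cbind(1, Xs[!tr, , drop = FALSE]) %*% beta)
    tibble::tibble(fold = f, rmse_test = sqrt(mean((y[!tr] - pred)^2)))
  })
  beta_full <- pinv_lsfit(Xs, y)
  pred_full <- drop(cbind(1, Xs) %*% beta_full)
  raw_slopes <- beta_full[-1] / sdev
  structure(list(
    feature = feature, predictors = targets, coefficients = beta_full,
    coefficients_raw = c(`(Intercept)` =
                           unname(beta_full[1] - sum(raw_slopes * mu)),
                         raw_slopes),
    cv = cv, best_fold = cv$fold[which.min(cv$rmse_test)],
    r2 = r_squared(y, pred_full), rmse = sqrt(mean((y - pred_full)^2)),
    n = n, scaling = list(mu = mu, sd = sdev), level = "condition"),
    class = "erk_regression")
}
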