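#' Stratified train/validation/test splits
#'
#' Builds `n_folds` cross-validation folds over cells. In each fold ~20% of
#' cells form the test set; the remaining 80% is split 80/20 into training
#' (64% of all cells) and validation (16%). Fold assignment is stratified so
#' each fold has roughly the same representation from each stratum (well and
#' condition by default).
#'
#' @param cells Cell table with `cell_id` and the stratification columns.
#' @param n_folds Number of folds (default 5).
#' @param seed RNG seed.
#' @param strata Column names to stratify on.
#' @return Tibble of class `erk_splits`: `fold`, `cell_id`, `role`
#'   (train/validation/test).
#' @export
make_splits <- function(cells, n_folds = 5, seed = 1,
                        strata = intersect(c("well", "condition"),
                                           names(cells))) {
  key <- if (length(strata)) {
    do.call(paste, c(cells[strata], sep = "|"))
  } else rep("all", nrow(cells))
  counts <- table(key)
  abort_if(any(counts < n_folds),
           sprintf("stratum too small for %d folds: %s", n_folds,
                   names(counts)[which.min(counts)]))
  with_seed(seed, {
    fold_of <- integer(nrow(cells))
    shuffled <- list()
    for (k in unique(key)) {
      idx <- sample(which(key == k))
      fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
      shuffled[[k]] <- idx
    }
    out <- purrr::map_dfr(seq_len(n_folds), function(f) {
      role <- rep("train", nrow(cells))
      role[fold_of == f] <- "test"
      # within each stratum, every n_folds-th remaining cell (fold-specific
      # offset) -> 1/n_folds of the remainder as validation (16% of total
      # at 5 folds)
      for (k in names(shuffled)) {
        rem <- shuffled[[k]][fold_of[shuffled[[k]]] != f]
        if (length(rem)) {
          start <- (f - 1) %% n_folds + 1
          role[rem[seq(min(start, length(rem)), length(rem),
                       by = n_folds)]] <- "validation"
        }
      }
      tibble::tibble(fold = f, cell_id = cells$cell_id, role = role)
    })
    class(out) <- c("erk_splits", class(out))
    out
  })
}

split_ids <- function(splits, f, which_role) {
  splits$cell_id[splits$fold == f & splits$role == which_role]
}

# Shared fitting/evaluation engine for the two linear forward models.
fit_linear_forward <- function(X, y, splits, model_class) {
  folds <- sort(unique(splits$fold))
  per_fold <- list()
  coefs <- list()
  for (f in folds) {
    tr <- intersect(split_ids(splits, f, "train"), rownames(X))
    va <- intersect(split_ids(splits, f, "validation"), rownames(X))
    te <- intersect(split_ids(splits, f, "test"), rownames(X))
    beta <- pinv_lsfit(X[tr, , drop = FALSE], y[tr])
    pred <- function(ids) {
      drop(cbind(1, X[ids, , drop = FALSE]) %*% beta)
    }
    per_fold[[f]] <- purrr::map_dfr(
      list(train = tr, validation = va, test = te),
      function(ids) {
        p <- pred(ids)
        tibble::tibble(r2 = r_squared(y[ids], p),
                       mse = mean((y[ids] - p)^2))
      }, .id = "split") |>
      dplyr::mutate(fold = f, .before = 1)
    coefs[[f]] <- beta
  }
  beta_full <- pinv_lsfit(X, y)
  structure(list(coefficients = beta_full, fold_coefficients = coefs,
                 metrics = dplyr::bind_rows(per_fold),
                 predictors = colnames(X)),
            class = c(model_class, "erk_forward"))
}

#' @export
print.erk_forward <- function(x, ...) {
  test <- dplyr::filter(x$metrics, .data$split == "test")
  cat(class(x)[1], ": ", length(x$predictors), " predictors; mean test R2 = ",
      signif(mean(test$r2), 3), "\n", sep = "")
  invisible(x)
}

#' Time-series linear model of endpoint stain levels
#'
#' Ordinary least squares with the activity at every timepoint as a separate
#' predictor. Exact collinearity is handled by the SVD pseudoinverse
#' (minimum-norm solution). Metrics are reported per fold on the training,
#' validation and held-out test cells; the returned coefficients are the fit
#' on all cells.
#'
#' @param traces Long trace table.
#' @param target Named numeric vector of the response per cell (names =
#'   cell ids), e.g. one stain column (typically log10).
#' @param splits Splits from [make_splits()].
#' @return `erk_ts_linear` object: `coefficients`, per-fold `metrics`
#'   (fold x split x r2/mse), `predictors`.
#' @export
fit_ts_linear <- function(traces, target, splits) {
  X <- trace_matrix(traces)
  X <- X[intersect(rownames(X), names(target)), , drop = FALSE]
  colnames(X) <- sprintf("t%g", attr(X, "t_min"))
  fit_linear_forward(X, target[rownames(X)], splits, "erk_ts_linear")
}

#' Featurized linear model of endpoint stain levels
#'
#' As [fit_ts_linear()], with the nine dynamic features as predictors.
#'
#' @param features Feature table from [erk_features()].
#' @param target Named response vector (names = cell ids).
#' @param splits Splits from [make_splits()].
#' @return `erk_feat_linear` object.
#' @export
fit_featurized_linear <- function(features, target, splits) {
  X <- as.matrix(features[, ERK_FEATURES])
  rownames(X) <- features$cell_id
  X <- X[intersect(rownames(X), names(target)), , drop = FALSE]
  fit_linear_forward(X, target[rownames(X)], splits, "erk_feat_linear")
}

#' @export
predict.erk_forward <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else {
    if (all(c("cell_id", "t_min") %in% names(newdata))) {
      trace_matrix(newdata)
    } else {
      m <- as.matrix(newdata[, object$predictors])
      rownames(m) <- newdata$cell_id
      m
    }
  }
  drop(cbind(1, X) %*% object$coefficients)
}

#' Restrict traces to a trailing window
#'
#' Keeps only the last `keep_last_n` timepoints of every trace — used to ask
#' how much of the endpoint signal is carried by late activity. The dropped
#' offset is recorded in the `offset_samples` attribute.
#'
#' @param traces Long trace table (shared time grid).
#' @param keep_last_n Number of trailing samples to keep (>= 1).
#' @return Truncated trace table.
#' @export
truncate_window <- function(traces, keep_last_n) {
  abort_if(keep_last_n <= 0, "`keep_last_n` must be positive")
  times <- sort(unique(traces$t_min))
  abort_if(keep_last_n > length(times),
           "`keep_last_n` exceeds the trace length")
  keep <- utils::tail(times, keep_last_n)
  out <- traces[traces$t_min %in% keep, ]
  attr(out, "offset_samples") <- as.integer(length(times) - keep_last_n)
  out
}
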