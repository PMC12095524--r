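#' Architecture of the 1-D convolutional regressor
#'
#' Two same-padding convolutional layers (16 channels, kernel 16) feeding
#' three fully connected layers (192, 64, 64) and a linear scalar output;
#' rectifier activations on all hidden layers.
#'
#' @param n_conv_layers Number of convolutional layers (fixed architecture
#'   currently supports 2).
#' @param channels Channels per convolutional layer.
#' @param kernel Kernel width (must not exceed the input length).
#' @param fc_sizes Widths of the fully connected layers.
#' @return Named list of class `cnn_spec`.
#' @export
cnn_spec <- function(n_conv_layers = 2, channels = 16, kernel = 16,
                     fc_sizes = c(192, 64, 64)) {
  abort_if(n_conv_layers != 2, "the architecture uses 2 convolutional layers")
  abort_if(length(fc_sizes) != 3, "three fully connected layers expected")
  structure(list(n_conv_layers = n_conv_layers, channels = channels,
                 kernel = kernel, fc_sizes = fc_sizes), class = "cnn_spec")
}

#' Training configuration for the convolutional regressor
#'
#' @param epochs Training epochs (default 100).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param l2_penalty L2 regularization added to weight gradients (default
#'   1e-3; 1e-2 is the alternative from the hyperparameter sweep grid).
#' @param batch_size Minibatch size (default 256).
#' @param seed Seed for weight initialization and minibatch order.
#' @return Named list of class `train_config`.
#' @export
train_config <- function(epochs = 100, learning_rate = 1e-3,
                         l2_penalty = 1e-3, batch_size = 256, seed = 1) {
  abort_if(epochs < 1, "`epochs` must be >= 1")
  abort_if(learning_rate <= 0 || l2_penalty < 0, "rates must be positive")
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 l2_penalty = l2_penalty, batch_size = batch_size,
                 seed = seed), class = "train_config")
}

init_cnn_weights <- function(L, spec, seed) {
  k <- spec$kernel; C <- spec$channels; fc <- spec$fc_sizes
  he <- function(r, c, fan) matrix(rnorm(r * c, 0, sqrt(2 / fan)), r, c)
  with_seed(seed, list(
    W1 = he(k, C, k), b1 = rep(0, C),
    W2 = he(k * C, C, k * C), b2 = rep(0, C),
    Wf1 = he(L * C, fc[1], L * C), bf1 = rep(0, fc[1]),
    Wf2 = he(fc[1], fc[2], fc[1]), bf2 = rep(0, fc[2]),
    Wf3 = he(fc[2], fc[3], fc[2]), bf3 = rep(0, fc[3]),
    Wo = he(fc[3], 1, fc[3]), bo = 0))
}

#' Fit the 1-D convolutional regressor
#'
#' Trains the network of [cnn_spec()] to predict an endpoint value from a
#' cell's activity trace. Inputs are z-scored with the global mean and
#' standard deviation of the whole trace matrix and targets are z-scored,
#' so reported mean squared errors are on the standardized scale. Training
#' uses Adam with mean-squared-error loss and L2 weight regularization;
#' minibatch order and weight initialization are seeded, so a fixed seed
#' reproduces the fit exactly. Metrics are computed on the fold's training,
#' validation and held-out test cells.
#'
#' @param traces Long trace table (all cells on one time grid).
#' @param target Named response vector (names = cell ids).
#' @param splits Splits from [make_splits()].
#' @param spec Architecture from [cnn_spec()].
#' @param config Optimization settings from [train_config()].
#' @param folds Which folds to train (default the first; each fold is a full
#'   training run).
#' @return `erk_cnn` object: `weights` (per fold), `metrics`, scaling
#'   constants, and the loss history.
#' @export
fit_erk_cnn <- function(traces, target, splits, spec = cnn_spec(),
                        config = train_config(), folds = 1) {
  X <- trace_matrix(traces)
  X <- X[intersect(rownames(X), names(target)), , drop = FALSE]
  y <- target[rownames(X)]
  L <- ncol(X)
  abort_if(spec$kernel > L, "kernel exceeds the input length")
  x_mu <- mean(X); x_sd <- sd(as.numeric(X))
  y_mu <- mean(y); y_sd <- sd(y)
  Xs <- t((X - x_mu) / x_sd)  # L x N, column per cell
  ys <- (y - y_mu) / y_sd

  metrics <- list(); weights <- list(); losses <- list()
  for (f in folds) {
    tr <- intersect(split_ids(splits, f, "train"), colnames(Xs))
    va <- intersect(split_ids(splits, f, "validation"), colnames(Xs))
    te <- intersect(split_ids(splits, f, "test"), colnames(Xs))
    w0 <- init_cnn_weights(L, spec, config$seed + f)
    fit <- cnn_train_cpp(Xs[, tr, drop = FALSE], ys[tr], w0, config$epochs,
                         config$learning_rate, config$l2_penalty,
                         config$batch_size, config$seed + f,
                         Xs[, va, drop = FALSE], ys[va])
    pr <- function(ids) as.numeric(
      cnn_predict_cpp(fit$weights, Xs[, ids, drop = FALSE], 256L))
    metrics[[as.character(f)]] <- purrr::map_dfr(
      list(train = tr, validation = va, test = te),
      function(ids) {
        p <- pr(ids)
        tibble::tibble(r2 = r_squared(ys[ids], p),
                       mse = mean((ys[ids] - p)^2))
      }, .id = "split") |>
      dplyr::mutate(fold = f, .before = 1)
    weights[[as.character(f)]] <- fit$weights
    losses[[as.character(f)]] <- tibble::tibble(
      fold = f, epoch = seq_len(config$epochs),
      train_loss = as.numeric(fit$train_loss),
      val_loss = as.numeric(fit$val_loss))
  }
  structure(list(weights = weights, metrics = dplyr::bind_rows(metrics),
                 loss = dplyr::bind_rows(losses), spec = spec,
                 config = config, t_min = attr(X, "t_min"),
                 scaling = list(x_mu = x_mu, x_sd = x_sd,
                                y_mu = y_mu, y_sd = y_sd)),
            class = "erk_cnn")
}

#' @export
print.erk_cnn <- function(x, ...) {
  test <- dplyr::filter(x$metrics, .data$split == "test")
  cat("1-D CNN regressor:", length(x$weights), "fold(s); test R2 =",
      paste(signif(test$r2, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.erk_cnn <- function(object, newdata, fold = NULL, rescale = TRUE,
                            ...) {
  X <- if (is.matrix(newdata)) newdata else trace_matrix(newdata)
  Xs <- t((X - object$scaling$x_mu) / object$scaling$x_sd)
  fold <- fold %||% names(object$weights)[1]
  p <- as.numeric(cnn_predict_cpp(object$weights[[as.character(fold)]],
                                  Xs, 256L))
  names(p) <- colnames(Xs)
  if (rescale) p * object$scaling$y_sd + object$scaling$y_mu else p
}

# Gradient of a model's scalar output with respect to each input timepoint,
# evaluated at the columns of Xs (standardized input space).
input_gradient <- function(model, Xs, fold) {
  if (inherits(model, "erk_cnn")) {
    cnn_input_grad_cpp(model$weights[[as.character(fold)]], Xs, 256L)
  } else if (inherits(model, "erk_forward")) {
    matrix(model$coefficients[-1], nrow(Xs), ncol(Xs))
  } else {
    rlang::abort("no input gradient available for this model class")
  }
}

#' Integrated-gradients attribution of timepoint importance
#'
#' Attributes the model's prediction for each cell to the individual input
#' timepoints by integrating the input gradient along the straight path from
#' a baseline trace to the cell's trace (midpoint Riemann approximation with
#' `n_steps` points). Attributions satisfy completeness: per cell they sum to
#' `f(x) - f(baseline)` up to the Riemann error. For a linear model the
#' result is exactly `w * (x - baseline)`. The default baseline is the
#' all-zeros trace in standardized units (the dataset-average trace value);
#' `"mean"` uses the per-timepoint dataset mean.
#'
#' @param model An `erk_cnn` or a linear forward model.
#' @param traces Long trace table (or trace matrix) of the cells to explain.
#' @param baseline `"zero"`, `"mean"`, or a numeric trace of the input
#'   length.
#' @param n_steps Riemann steps (>= 8; default 64).
#' @param fold Which trained fold of an `erk_cnn` to explain.
#' @return Object of class `erk_attribution`: per-cell matrix
#'   (`attributions`), the cell-averaged `map` tibble, and the completeness
#'   residuals.
#' @export
integrated_gradients <- function(model, traces, baseline = "zero",
                                 n_steps = 64, fold = NULL) {
  abort_if(n_steps < 8, "`n_steps` must be >= 8")
  X <- if (is.matrix(traces)) traces else trace_matrix(traces)
  t_min <- attr(X, "t_min") %||% seq_len(ncol(X))
  cnn <- inherits(model, "erk_cnn")
  Xs <- if (cnn) {
    t((X - model$scaling$x_mu) / model$scaling$x_sd)
  } else t(X)
  fold <- fold %||% if (cnn) names(model$weights)[1] else 1
  b <- if (is.numeric(baseline)) {
    abort_if(length(baseline) != nrow(Xs), "baseline length mismatch")
    baseline
  } else if (baseline == "zero") {
    rep(0, nrow(Xs))
  } else if (baseline == "mean") {
    rowMeans(Xs)
  } else rlang::abort("unknown baseline policy")

  diffs <- Xs - b
  total <- matrix(0, nrow(Xs), ncol(Xs))
  for (s in seq_len(n_steps)) {
    alpha <- (s - 0.5) / n_steps
    total <- total + input_gradient(model, b + alpha * diffs, fold)
  }
  attributions <- diffs * total / n_steps

  f_x <- if (cnn) {
    as.numeric(cnn_predict_cpp(model$weights[[as.character(fold)]], Xs, 256L))
  } else drop(cbind(1, t(Xs)) %*% model$coefficients)
  f_b <- if (cnn) {
    as.numeric(cnn_predict_cpp(model$weights[[as.character(fold)]],
                               matrix(b, ncol = 1), 256L))
  } else drop(c(1, b) %*% model$coefficients)
  completeness <- colSums(attributions) - (f_x - f_b)

  structure(list(
    attributions = t(attributions),  # cells x timepoints
    map = tibble::tibble(t_min = t_min, importance = rowMeans(attributions)),
    completeness = completeness, baseline = b, n_steps = n_steps),
    class = "erk_attribution")
}

#' @export
print.erk_attribution <- function(x, ...) {
  cat("Integrated-gradients attribution:", nrow(x$attributions), "cells x",
      ncol(x$attributions), "timepoints; max |completeness residual| =",
      signif(max(abs(x$completeness)), 3), "\n")
  invisible(x)
}
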