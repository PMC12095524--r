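make_linear_fixture <- function(n = 120, L = 40, seed = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * L), n, L)
  ids <- sprintf("c%03d", 1:n)
  rownames(X) <- ids
  t_min <- seq(0, by = 6, length.out = L)
  traces <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(cell_id = ids[i], t_min = t_min, activity = X[i, ])
  })
  cells <- tibble::tibble(cell_id = ids,
                          well = rep(c("w1", "w2"), length.out = n),
                          condition = "a")
  list(X = X, traces = traces, cells = cells, ids = ids)
}

test_that("splits are disjoint, exhaustive, stratified, and reproducible", {
  set.seed(1)
  cells <- tibble::tibble(cell_id = sprintf("c%04d", 1:1000),
                          well = rep(sprintf("w%d", 1:10), 100),
                          condition = rep(c("a", "b"), 500))
  sp <- make_splits(cells, n_folds = 5, seed = 3)
  test_sets <- lapply(1:5, function(f) split_ids <- sp$cell_id[
    sp$fold == f & sp$role == "test"])
  expect_identical(sort(unlist(test_sets)), sort(cells$cell_id))
  expect_identical(sum(duplicated(unlist(test_sets))), 0L)
  sizes <- lengths(test_sets)
  expect_true(all(abs(sizes - 200) <= 10))
  # role fractions per fold
  tab <- table(sp$role[sp$fold == 1]) / nrow(cells)
  expect_equal(unname(tab["test"]), 0.2, tolerance = 0.02)
  expect_equal(unname(tab["validation"]), 0.16, tolerance = 0.02)
  # stratum proportions in each test set within 2% of global
  for (f in 1:5) {
    ids <- sp$cell_id[sp$fold == f & sp$role == "test"]
    w <- cells$well[match(ids, cells$cell_id)]
    expect_true(all(abs(table(w) / length(ids) - 0.1) < 0.02))
  }
  expect_identical(make_splits(cells, seed = 3), sp)
  expect_error(make_splits(cells[1:8, ], n_folds = 5), "stratum")
})

test_that("time-series linear regression recovers generating weights", {
  fx <- make_linear_fixture()
  w <- rnorm(ncol(fx$X))
  y <- drop(fx$X %*% w) + 1.5
  names(y) <- fx$ids
  sp <- make_splits(fx$cells, n_folds = 5, seed = 1)
  fit <- fit_ts_linear(fx$traces, y, sp)
  expect_lt(max(abs(fit$coefficients[-1] - w)), 1e-6)
  expect_equal(unname(fit$coefficients[1]), 1.5, tolerance = 1e-6)
  expect_equal(ols_oracle(fx$X, y), unname(fit$coefficients),
               tolerance = 1e-8)
  test_r2 <- dplyr::filter(fit$metrics, .data$split == "test")$r2
  expect_true(all(test_r2 > 1 - 1e-9))

  # pure-noise target: test R^2 near zero or below
  y2 <- setNames(rnorm(length(y)), names(y))
  fit2 <- fit_ts_linear(fx$traces, y2, sp)
  expect_lt(mean(dplyr::filter(fit2$metrics, .data$split == "test")$r2), 0.05)
})

test_that("featurized linear model matches the closed form", {
  ds <- small_dataset()
  f <- erk_features(ds$traces)
  y <- setNames(2 * f$mean + 1, f$cell_id)
  sp <- make_splits(ds$cells, n_folds = 5, seed = 2)
  fit <- fit_featurized_linear(f, y, sp)
  expect_equal(unname(fit$coefficients["mean"]), 2, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 1, tolerance = 1e-6)
  expect_lt(max(abs(fit$coefficients[setdiff(names(fit$coefficients),
                                             c("(Intercept)", "mean"))])),
            1e-6)
  expect_true(all(dplyr::filter(fit$metrics,
                                .data$split == "test")$r2 > 1 - 1e-9))
  set.seed(4)
  y_sh <- setNames(sample(y), names(y))
  fit_sh <- fit_featurized_linear(f, y_sh, sp)
  expect_lt(mean(dplyr::filter(fit_sh$metrics, .data$split == "test")$r2),
            0.1)
})

test_that("window truncation keeps the trailing samples", {
  ds <- small_dataset()
  tr <- truncate_window(ds$traces, 150)
  expect_identical(length(unique(tr$t_min)), 150L)
  expect_identical(attr(tr, "offset_samples"), 40L)
  expect_equal(min(tr$t_min), 40 * 6)
  full <- truncate_window(ds$traces, 190)
  expect_identical(nrow(full), nrow(ds$traces))
  expect_error(truncate_window(ds$traces, 0), "positive")
  expect_error(truncate_window(ds$traces, 191), "length")
})

test_that("the CNN learns a smooth functional and trains reproducibly", {
  set.seed(6)
  n <- 400; L <- 190
  ids <- sprintf("c%03d", 1:n)
  t_min <- seq(0, by = 6, length.out = L)
  # smooth trace-like inputs (AR(1) over time, as activity traces are)
  X <- t(sapply(seq_len(n), function(i) {
    x <- numeric(L)
    x[1] <- rnorm(1, 0.5, 0.2)
    for (j in 2:L) x[j] <- 0.5 + 0.95 * (x[j - 1] - 0.5) + rnorm(1, 0, 0.06)
    x
  }))
  traces <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(cell_id = ids[i], t_min = t_min, activity = X[i, ])
  })
  cells <- tibble::tibble(cell_id = ids, well = "w", condition = "a")
  y <- setNames(rowMeans(X) + rnorm(n, 0, 0.002), ids)
  sp <- make_splits(cells, n_folds = 5, seed = 1)
  # small batches so the optimizer takes enough steps at this sample size
  cfg <- train_config(epochs = 60, batch_size = 32, seed = 2)
  fit <- fit_erk_cnn(traces, y, sp, config = cfg)
  expect_gt(dplyr::filter(fit$metrics, .data$split == "test")$r2, 0.9)
  fit2 <- fit_erk_cnn(traces, y, sp, config = cfg)
  expect_identical(fit$loss$train_loss, fit2$loss$train_loss)
  # prediction round trip on the original scale
  p <- predict(fit, traces)
  expect_gt(cor(p[ids], y), 0.95)
  expect_error(fit_erk_cnn(traces, y, sp, spec = cnn_spec(kernel = 500)),
               "kernel")
})

test_that("integrated gradients are exact for linear models", {
  fx <- make_linear_fixture(n = 60, L = 30)
  w <- rnorm(30)
  y <- drop(fx$X %*% w)
  names(y) <- fx$ids
  sp <- make_splits(fx$cells, n_folds = 5, seed = 1)
  fit <- fit_ts_linear(fx$traces, y, sp)
  ig <- integrated_gradients(fit, fx$traces, baseline = "zero", n_steps = 16)
  want <- sweep(fx$X, 2, fit$coefficients[-1], "*")  # w (x - 0)
  expect_equal(unname(ig$attributions[fx$ids, ]), unname(want[fx$ids, ]),
               tolerance = 1e-8)
  expect_lt(max(abs(ig$completeness)), 1e-8)
  expect_error(integrated_gradients(fit, fx$traces, n_steps = 4), "n_steps")
})

test_that("integrated gradients on the CNN satisfy completeness and converge", {
  set.seed(8)
  n <- 120; L <- 60
  ids <- sprintf("c%03d", 1:n)
  t_min <- seq(0, by = 6, length.out = L)
  X <- matrix(rnorm(n * L, 0.5, 0.3), n, L)
  traces <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(cell_id = ids[i], t_min = t_min, activity = X[i, ])
  })
  cells <- tibble::tibble(cell_id = ids, well = "w", condition = "a")
  y <- setNames(rowMeans(X), ids)
  sp <- make_splits(cells, n_folds = 5, seed = 1)
  fit <- fit_erk_cnn(traces, y, sp,
                     config = train_config(epochs = 15, batch_size = 32,
                                           seed = 3))
  # a rectifier network is piecewise linear, so the midpoint Riemann sum
  # carries O(1/n_steps) error from the activation kinks; completeness and
  # refinement are therefore checked at the corresponding relative scale
  ig <- integrated_gradients(fit, traces, n_steps = 128)
  scale_out <- max(abs(rowSums(ig$attributions)))
  expect_lt(max(abs(ig$completeness)) / scale_out, 0.02)
  ig2 <- integrated_gradients(fit, traces, n_steps = 256)
  expect_lt(max(abs(ig2$completeness)) / scale_out, 0.02)
  denom <- max(abs(ig2$attributions))
  expect_lt(max(abs(ig$attributions - ig2$attributions)) / denom, 0.02)
})
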