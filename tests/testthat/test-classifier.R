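adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  si <- comb2(rowSums(tab)); sj <- comb2(colSums(tab))
  sij <- comb2(as.vector(tab)); n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

test_that("prototype clustering recovers the generating archetypes", {
  ds <- small_dataset()
  tr <- qc_traces(ds$traces)
  proto <- cluster_prototypes(tr, k = 5, seed = 3)
  truth <- ds$cells$true_class[match(proto$labels$cell_id,
                                     ds$cells$cell_id)]
  expect_gt(adjusted_rand(proto$labels$class, truth), 0.9)
  # centroid is the mean of its members
  m <- trace_matrix <- tidyr::pivot_wider(tr, names_from = "t_min",
                                          values_from = "activity")
  X <- as.matrix(m[, -1])
  for (k in 1:5) {
    members <- proto$labels$class[match(m$cell_id,
                                        proto$labels$cell_id)] == k
    expect_equal(unname(colMeans(X[members, , drop = FALSE])),
                 unname(proto$centroids[k, ]), tolerance = 1e-10)
  }
  expect_error(cluster_prototypes(tr, k = 1), "k")
})

test_that("the correlation filter keeps faithful members only", {
  ds <- small_dataset()
  proto <- cluster_prototypes(qc_traces(ds$traces), k = 5, seed = 3)
  keep <- filter_prototype_members(proto, r_min = 0.7)
  expect_true(all(proto$labels$r[keep] >= 0.7))
  expect_true(all(proto$labels$r[!keep] < 0.7))
  # a cell equal to its centroid has r = 1; its negation (about the mean)
  # has r = -1
  cent <- proto$centroids[1, ]
  fake <- dplyr::bind_rows(
    tibble::tibble(cell_id = "same", t_min = proto$t_min, activity = cent),
    tibble::tibble(cell_id = "anti", t_min = proto$t_min,
                   activity = 2 * mean(cent) - cent))
  both <- dplyr::bind_rows(ds$traces, fake)
  proto2 <- cluster_prototypes(both, k = 5, seed = 3)
  lab <- proto2$labels
  expect_gt(lab$r[lab$cell_id == "same"], 0.99)
  expect_error(filter_prototype_members(proto, r_min = 1.0000001), "class")
})

test_that("boosting separates Gaussian classes and shuffles fall to chance", {
  set.seed(15)
  n_per <- 60; k <- 4
  centers <- matrix(rnorm(k * 3, 0, 4), k, 3)
  stains <- purrr::map_dfr(1:k, function(cl) {
    tibble::tibble(cell_id = sprintf("c%d_%02d", cl, 1:n_per),
                   s1 = 10^(centers[cl, 1] / 4 + rnorm(n_per, 0, 0.15)),
                   s2 = 10^(centers[cl, 2] / 4 + rnorm(n_per, 0, 0.15)),
                   s3 = 10^(centers[cl, 3] / 4 + rnorm(n_per, 0, 0.15)))
  })
  labels <- tibble::tibble(cell_id = stains$cell_id,
                           class = rep(1:k, each = n_per))
  clf <- fit_history_classifier(stains, labels, n_rounds = 60, folds = 5,
                                seed = 2)
  expect_gt(clf$accuracy, 0.95)
  expect_identical(unname(rowSums(clf$confusion)),
                   as.numeric(table(labels$class)[
                     match(rownames(clf$confusion),
                           names(table(labels$class)))] / 5))
  shuf <- labels
  set.seed(16)
  shuf$class <- sample(shuf$class)
  clf_sh <- fit_history_classifier(stains, shuf, n_rounds = 40, folds = 5,
                                   seed = 2)
  expect_lt(clf_sh$cv_accuracy, 1 / k + 0.12)
})

test_that("predictor importance ranks an uninformative column last", {
  set.seed(17)
  n_per <- 50
  # L-shaped layout: separating class 2 needs info1, class 3 needs info2,
  # so both informative stains must be used; junk carries nothing
  centers <- list(c(0, 0), c(1.2, 0), c(0, 1.2))
  stains <- purrr::map_dfr(1:3, function(cl) {
    tibble::tibble(cell_id = sprintf("c%d_%02d", cl, 1:n_per),
                   info1 = 10^(centers[[cl]][1] + rnorm(n_per, 0, 0.15)),
                   info2 = 10^(centers[[cl]][2] + rnorm(n_per, 0, 0.15)),
                   junk = 10^rnorm(n_per, 0, 0.4))
  })
  labels <- tibble::tibble(cell_id = stains$cell_id,
                           class = rep(1:3, each = n_per))
  clf <- fit_history_classifier(stains, labels, n_rounds = 40, folds = 5,
                                seed = 4)
  imp <- predictor_importance(clf)
  expect_true(all(imp >= 0))
  expect_lt(imp["junk"], min(imp[c("info1", "info2")]))
  # column order invariance
  clf2 <- fit_history_classifier(stains[, c("cell_id", "junk", "info2",
                                            "info1")],
                                 labels, n_rounds = 40, folds = 5, seed = 4)
  imp2 <- predictor_importance(clf2)
  expect_equal(imp2[names(imp)], imp, tolerance = 1e-9)
})

test_that("hexagonal regions partition cells and keep centers fixed", {
  cells <- tibble::tibble(cell_id = c("a", "b", "c"),
                          x_um = c(0, 500, 500), y_um = c(0, 400, 401))
  hr <- hex_regions(cells, 50)
  expect_identical(nrow(hr), 3L)
  expect_identical(anyDuplicated(hr$cell_id), 0L)
  # a cell exactly at a hex center maps to that hex
  expect_identical(hr$region_id[1], "h0_0")
  expect_lt(abs(hr$region_x[1]) + abs(hr$region_y[1]), 1e-9)
  # neighbors within one radius share a region more often than not
  expect_identical(hr$region_id[2], hr$region_id[3])
  # every assignment is within one circumradius of its center
  d <- sqrt((cells$x_um - hr$region_x)^2 + (cells$y_um - hr$region_y)^2)
  expect_true(all(d <= 50 + 1e-9))
  expect_error(hex_regions(cells, 0), "radius")
  expect_error(hex_regions(dplyr::mutate(cells, x_um = NaN), 50), "finite")
})

test_that("tiny regions reproduce single-cell behavior; regional runs work", {
  ds <- small_dataset()
  # radius small enough that every region is a singleton
  hr <- hex_regions(ds$cells, 0.5)
  expect_identical(length(unique(hr$region_id)), nrow(ds$cells))
  reg <- regional_pipeline(ds, radius_um = 0.5, k = 5, seed = 5,
                           n_rounds = 30, folds = 5)
  single_proto <- cluster_prototypes(ds$traces, k = 5, seed = 5)
  # singleton-region clustering equals single-cell clustering up to label
  # permutation
  map <- reg$prototypes$labels
  map$cell <- sub("^[^|]*\\|", "", map$cell_id)
  # region ids are well-qualified; recover members via the regions table
  members <- reg$regions
  m <- match(members$region_id, map$cell_id)
  reg_class <- map$class[m]
  sc_class <- single_proto$labels$class[
    match(members$cell_id, single_proto$labels$cell_id)]
  expect_gt(adjusted_rand(reg_class, sc_class), 0.999)
})

test_that("whole-image model runs on enough wells and is deterministic", {
  ds <- simulate_plate(default_layout(n_cells = 12, replicates = 4),
                       seed = 44)
  wm <- whole_image_model(ds, k = 5, seed = 2)
  expect_identical(wm$n_samples, 20L)
  expect_true(wm$cv_accuracy >= 0 && wm$cv_accuracy <= 1)
  wm2 <- whole_image_model(ds, k = 5, seed = 2)
  expect_identical(wm$cv_accuracy, wm2$cv_accuracy)
  small <- simulate_plate(default_layout(n_cells = 8, replicates = 2),
                          seed = 44)
  expect_error(whole_image_model(small), "20 images")
})

test_that("annotation labels complete cells and flags incomplete ones", {
  ds <- small_dataset()
  proto <- cluster_prototypes(ds$traces, k = 5, seed = 1)
  keep <- filter_prototype_members(proto, 0.7)
  clf <- fit_history_classifier(ds$stains,
                                proto$labels[keep, c("cell_id", "class")],
                                n_rounds = 30, folds = 5, seed = 1)
  stains <- ds$stains
  stains$Fra1[1:5] <- NA
  ov <- annotate_histories(clf, stains, ds$cells)
  expect_identical(nrow(ov), nrow(ds$cells))
  expect_true(all(!ov$labeled[match(stains$cell_id[1:5], ov$cell_id)]))
  expect_true(all(ov$labeled[!ov$cell_id %in% stains$cell_id[1:5]]))
  # round trip through disk preserves labels
  tmp <- tempfile(fileext = ".csv")
  write.csv(ov, tmp, row.names = FALSE)
  back <- utils::read.csv(tmp)
  expect_identical(as.character(back$pred_class[!is.na(back$pred_class)]),
                   as.character(ov$pred_class[ov$labeled]))
  unlink(tmp)
})
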