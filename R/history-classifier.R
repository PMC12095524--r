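#' Cluster activity traces into history prototypes
#'
#' k-means on the raw trace vectors (no per-cell normalization, so amplitude
#' differences count), best of `n_init` restarts by within-cluster sum of
#' squares. Each cell also receives the Pearson correlation between its trace
#' and its class centroid, used by [filter_prototype_members()].
#'
#' @param traces Long trace table (equal-length traces).
#' @param k Number of prototypes (default 5).
#' @param seed RNG seed for the restarts.
#' @param n_init Number of random restarts.
#' @param scale_traces Optionally z-score each trace before clustering
#'   (default `FALSE`).
#' @return Object of class `erk_prototypes`: `centroids` (k x timepoints),
#'   `labels` tibble (`cell_id`, `class`, `r`), `t_min`, `wcss`.
#' @export
cluster_prototypes <- function(traces, k = 5, seed = 1, n_init = 5,
                               scale_traces = FALSE) {
  m <- trace_matrix(traces)
  abort_if(k < 2, "`k` must be >= 2")
  abort_if(k > nrow(m), "`k` exceeds the number of cells")
  mc <- if (scale_traces) t(scale(t(m))) else m
  km <- with_seed(seed,
                  kmeans(mc, centers = k, nstart = n_init, iter.max = 100))
  r <- vapply(seq_len(nrow(mc)), function(i) {
    suppressWarnings(cor(mc[i, ], km$centers[km$cluster[i], ]))
  }, numeric(1))
  r[!is.finite(r)] <- 0
  structure(list(
    centroids = km$centers,
    labels = tibble::tibble(cell_id = rownames(m),
                            class = as.integer(km$cluster), r = r),
    t_min = attr(m, "t_min"), k = k, wcss = km$tot.withinss,
    scale_traces = scale_traces), class = "erk_prototypes")
}

#' @export
print.erk_prototypes <- function(x, ...) {
  cat("ERK history prototypes: k =", x$k, "; members:",
      paste(table(x$labels$class), collapse = ", "), "\n")
  invisible(x)
}

#' Filter cells by correlation to their prototype
#'
#' Keeps cells whose trace correlates with its class centroid at or above
#' `r_min` (default 0.7). Dropped cells are excluded from classifier training but can
#' still be predicted at annotation time.
#'
#' @param prototypes An `erk_prototypes` object.
#' @param r_min Minimum Pearson correlation.
#' @return Logical vector (kept mask) aligned with `prototypes$labels`.
#' @export
filter_prototype_members <- function(prototypes, r_min = 0.7) {
  keep <- prototypes$labels$r >= r_min
  lost <- setdiff(unique(prototypes$labels$class),
                  unique(prototypes$labels$class[keep]))
  abort_if(length(lost) > 0,
           sprintf("class %s lost all members at r_min = %g",
                   paste(lost, collapse = ", "), r_min))
  keep
}

#' Boosted multiclass classifier of signaling history
#'
#' Trains an AdaBoost.M2 ensemble of shallow decision trees (500 rounds by
#' default) to predict each cell's history class from its stain panel
#' (log10 intensities). Model selection follows a best-test-fold rule:
#' 10-fold cross-validation is run, the fold model with the lowest test error
#' is kept, and its test fold provides the reported confusion matrix; the
#' cross-validated accuracy over all folds is reported alongside.
#'
#' @param stains Wide stain table (`cell_id` + target columns).
#' @param labels Tibble (`cell_id`, `class`) of training labels.
#' @param n_rounds Boosting rounds.
#' @param folds Number of CV folds.
#' @param seed RNG seed.
#' @param maxdepth Weak-learner tree depth.
#' @param log10_stains Model log10 stain values (default `TRUE`).
#' @return Object of class `erk_history_classifier`: the selected `ensemble`,
#'   `accuracy` (best fold test accuracy), `cv_accuracy` (mean over folds),
#'   `per_class` accuracies, `confusion`, `importance`, `targets`.
#' @export
fit_history_classifier <- function(stains, labels, n_rounds = 500, folds = 10,
                                   seed = 1, maxdepth = 2,
                                   log10_stains = TRUE) {
  targets <- stain_targets(stains)
  d <- stains[match(labels$cell_id, stains$cell_id), targets, drop = FALSE]
  ok <- complete.cases(d)
  d <- d[ok, , drop = FALSE]
  y <- factor(labels$class[ok])
  if (log10_stains) d <- log10(d)
  n <- nrow(d)
  cnt <- table(y)
  abort_if(any(cnt < folds),
           sprintf("class %s has fewer members than folds",
                   names(cnt)[which.min(cnt)]))
  fold_of <- with_seed(seed, {
    f <- integer(n)
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    f
  })
  fits <- list(); err <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    fit <- adaboost_m2(d[tr, , drop = FALSE], y[tr], n_rounds = n_rounds,
                       maxdepth = maxdepth, seed = seed + f)
    pred <- predict.adaboost_m2(fit, d[!tr, , drop = FALSE])
    err[f] <- mean(pred != y[!tr])
    fits[[f]] <- fit
  }
  best <- which.min(err)
  te <- fold_of == best
  pred <- predict.adaboost_m2(fits[[best]], d[te, , drop = FALSE])
  confusion <- table(truth = y[te], predicted = pred)
  per_class <- diag(confusion) / pmax(rowSums(confusion), 1)
  structure(list(
    ensemble = fits[[best]], best_fold = best, accuracy = 1 - err[best],
    cv_accuracy = 1 - mean(err), fold_errors = err,
    per_class = per_class, confusion = confusion,
    importance = adaboost_importance(fits[[best]], targets),
    targets = targets, log10_stains = log10_stains,
    classes = levels(y), n_test = sum(te)), class = "erk_history_classifier")
}

#' @export
print.erk_history_classifier <- function(x, ...) {
  cat("Signaling-history classifier:", length(x$classes), "classes;",
      "best-fold test accuracy", signif(x$accuracy, 3),
      "(CV mean", paste0(signif(x$cv_accuracy, 3), ")"), "\n")
  invisible(x)
}

#' @export
predict.erk_history_classifier <- function(object, stains, ...) {
  d <- stains[, object$targets, drop = FALSE]
  ok <- complete.cases(d)
  out <- factor(rep(NA_character_, nrow(d)), levels = object$classes)
  if (any(ok)) {
    dd <- d[ok, , drop = FALSE]
    if (object$log10_stains) dd <- log10(dd)
    out[ok] <- predict.adaboost_m2(object$ensemble, dd)
  }
  out
}

#' Per-stain predictor importance
#'
#' Summed split improvement of each stain across all weak learners of the
#' selected ensemble; non-negative, zero for predictors never used in a
#' split, invariant to column order.
#'
#' @param model An `erk_history_classifier`.
#' @return Named numeric vector.
#' @export
predictor_importance <- function(model) {
  abort_if(!inherits(model, "erk_history_classifier"), "untrained model")
  model$importance
}

#' Assign cells to hexagonal regions
#'
#' Pointy-top hexagonal lattice with the given circumradius, anchored at the
#' field origin; each cell is assigned to the nearest hexagon center (cube
#' rounding of fractional axial coordinates), so the regions partition the
#' field.
#'
#' @param cells Table with `cell_id`, `x_um`, `y_um`.
#' @param radius_um Hexagon circumradius in micrometers (default 50).
#' @return Tibble: `cell_id`, `region_id`, `region_x`, `region_y`.
#' @export
hex_regions <- function(cells, radius_um = 50) {
  abort_if(radius_um <= 0, "`radius_um` must be positive")
  abort_if(any(!is.finite(cells$x_um) | !is.finite(cells$y_um)),
           "coordinates must be finite")
  x <- cells$x_um; y <- cells$y_um
  q <- (sqrt(3) / 3 * x - 1 / 3 * y) / radius_um
  r <- (2 / 3 * y) / radius_um
  # cube rounding
  xc <- q; zc <- r; yc <- -xc - zc
  rx <- round(xc); ry <- round(yc); rz <- round(zc)
  dx <- abs(rx - xc); dy <- abs(ry - yc); dz <- abs(rz - zc)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  cx <- radius_um * sqrt(3) * (rx + rz / 2)
  cy <- radius_um * 3 / 2 * rz
  tibble::tibble(cell_id = cells$cell_id,
                 region_id = sprintf("h%d_%d", as.integer(rx), as.integer(rz)),
                 region_x = cx, region_y = cy)
}

# Region-mean traces and stains for a dataset restricted to `cell_ids`.
region_aggregate <- function(dataset, regions, cell_ids = NULL) {
  cell_ids <- cell_ids %||% dataset$cells$cell_id
  reg <- regions[regions$cell_id %in% cell_ids, ]
  tr <- dataset$traces |>
    dplyr::inner_join(reg[, c("cell_id", "region_id")], by = "cell_id") |>
    dplyr::group_by(.data$region_id, .data$t_min) |>
    dplyr::summarise(activity = mean(.data$activity), .groups = "drop") |>
    dplyr::rename(cell_id = "region_id")  # region id doubles as unit id
  targets <- stain_targets(dataset$stains)
  st <- dataset$stains |>
    dplyr::inner_join(reg[, c("cell_id", "region_id")], by = "cell_id") |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(targets), mean),
                     .groups = "drop") |>
    dplyr::rename(cell_id = "region_id")
  list(traces = tr, stains = st)
}

#' Regional signaling-history pipeline
#'
#' Repeats prototype clustering and classification on hexagonal region
#' averages: member cells' traces and stains are averaged per region, regions
#' are clustered into k prototypes, filtered at `r_min`, and a boosted
#' classifier is trained on the region-mean stains.
#'
#' @param dataset An `erk_dataset` (or list with `traces`, `cells`,
#'   `stains`).
#' @param radius_um Hexagon circumradius.
#' @param k Number of prototypes.
#' @param seed RNG seed.
#' @param r_min Correlation filter threshold.
#' @param n_rounds Boosting rounds.
#' @param folds Requested CV folds; reduced with a warning when there are too
#'   few regions.
#' @return List: `classifier`, `prototypes`, `regions`, `n_regions`.
#' @export
regional_pipeline <- function(dataset, radius_um = 50, k = 5, seed = 1,
                              r_min = 0.7, n_rounds = 500, folds = 10) {
  regions <- hex_regions(dataset$cells, radius_um)
  # regions never straddle wells: qualify region ids by well
  regions$region_id <- paste(
    dataset$cells$well[match(regions$cell_id, dataset$cells$cell_id)],
    regions$region_id, sep = "|")
  agg <- region_aggregate(dataset, regions)
  proto <- cluster_prototypes(agg$traces, k = k, seed = seed)
  keep <- filter_prototype_members(proto, r_min)
  labels <- proto$labels[keep, c("cell_id", "class")]
  min_class <- min(table(labels$class))
  if (min_class < folds) {
    warning(sprintf("reducing folds from %d to %d (smallest class)",
                    folds, max(2, min_class)))
    folds <- max(2, min_class)
  }
  clf <- fit_history_classifier(agg$stains, labels, n_rounds = n_rounds,
                                folds = folds, seed = seed)
  list(classifier = clf, prototypes = proto, regions = regions,
       n_regions = length(unique(regions$region_id)))
}

#' Whole-image history model
#'
#' One sample per image (well): traces and stains are averaged per well,
#' wells are clustered into k prototypes, and a single decision tree predicts
#' the class from the well-mean stains (sample sizes are too small for an
#' ensemble). Cross-validation uses as many folds as the data permit.
#'
#' @param dataset An `erk_dataset`.
#' @param k Number of prototypes.
#' @param seed RNG seed.
#' @param folds Requested CV folds.
#' @return List: `accuracy`, `cv_accuracy`, `n_samples`, `tree`,
#'   `prototypes`.
#' @export
whole_image_model <- function(dataset, k = 5, seed = 1, folds = 10) {
  wells <- unique(dataset$cells$well)
  abort_if(length(wells) < 20, "need at least 20 images (wells)")
  targets <- stain_targets(dataset$stains)
  by_well <- dataset$cells[, c("cell_id", "well")]
  tr <- dataset$traces |>
    dplyr::inner_join(by_well, by = "cell_id") |>
    dplyr::group_by(.data$well, .data$t_min) |>
    dplyr::summarise(activity = mean(.data$activity), .groups = "drop") |>
    dplyr::rename(cell_id = "well")
  st <- dataset$stains[, c("cell_id", targets)] |>
    dplyr::inner_join(by_well, by = "cell_id") |>
    dplyr::group_by(.data$well) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(targets), mean),
                     .groups = "drop") |>
    dplyr::rename(cell_id = "well")
  proto <- cluster_prototypes(tr, k = k, seed = seed)
  y <- factor(proto$labels$class[match(st$cell_id, proto$labels$cell_id)])
  abort_if(length(unique(y)) < 2, "fewer than 2 classes represented")
  d <- log10(st[, targets])
  folds <- max(2, min(folds, min(table(y))))
  fold_of <- with_seed(seed, {
    f <- integer(nrow(d))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    f
  })
  acc <- vapply(seq_len(folds), function(f) {
    tree <- fit_weak_tree(d[fold_of != f, , drop = FALSE], y[fold_of != f],
                          rep(1, sum(fold_of != f)), maxdepth = 30)
    pred <- predict(tree, d[fold_of == f, , drop = FALSE], type = "class")
    mean(pred == y[fold_of == f])
  }, numeric(1))
  tree <- fit_weak_tree(d, y, rep(1, nrow(d)), maxdepth = 30)
  list(accuracy = max(acc), cv_accuracy = mean(acc),
       n_samples = length(wells), tree = tree, prototypes = proto)
}

#' Overlay table of inferred signaling histories
#'
#' Joins class predictions onto spatial coordinates for plotting over an
#' image. Cells lacking complete predictor data remain unlabeled and are
#' flagged.
#'
#' @param model An `erk_history_classifier`.
#' @param stains Wide stain table.
#' @param cells Table with `cell_id`, `x_um`, `y_um`.
#' @return Tibble: `cell_id`, `x_um`, `y_um`, `pred_class`, `labeled`.
#' @export
annotate_histories <- function(model, stains, cells) {
  pred <- predict(model, stains)
  out <- tibble::tibble(
    cell_id = stains$cell_id,
    pred_class = pred, labeled = !is.na(pred))
  dplyr::left_join(cells[, c("cell_id", "x_um", "y_um")], out, by = "cell_id")
}
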