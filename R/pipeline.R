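#' Default end-to-end run configuration
#'
#' Nested list of every stage's parameters. All values can be overridden from
#' a YAML or JSON file ([load_config()]); unknown keys are rejected so typos
#' fail loudly.
#'
#' @return Named list of class `erk_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1,
    layout = list(n_cells = 60, replicates = 3, field_um = c(702, 785)),
    generator = list(noise_cv = 0.1, batch_sdlog10 = 0.1),
    qc = list(min_hours = 15),
    features = list(prominence_fraction = 0.1),
    forward = list(n_folds = 5, cnn = FALSE, epochs = 30),
    reverse = list(folds = 10),
    classifier = list(k = 5, r_min = 0.7, n_rounds = 200, folds = 10,
                      radius_um = 50),
    output = list(verbose = FALSE)
  ), class = "erk_config")
}

merge_config <- function(defaults, override, path = character()) {
  for (nm in names(override)) {
    here <- paste(c(path, nm), collapse = "$")
    abort_if(!nm %in% names(defaults),
             sprintf("unknown configuration key `%s`", here))
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      abort_if(!is.list(override[[nm]]),
               sprintf("`%s` must be a block of settings", here))
      defaults[[nm]] <- merge_config(defaults[[nm]], override[[nm]],
                                     c(path, nm))
    } else {
      defaults[[nm]] <- override[[nm]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads YAML or JSON, fills unset values with [default_config()] and rejects
#' unknown keys, reporting the offending key path. An empty file yields the
#' defaults. Configurations round-trip losslessly through
#' [yaml::write_yaml()].
#'
#' @param path Configuration file (`.yaml`/`.yml` or `.json`).
#' @return Validated `erk_config`.
#' @export
load_config <- function(path) {
  abort_if(!file.exists(path), sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  cfg <- merge_config(unclass(default_config()), raw)
  structure(cfg, class = "erk_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Chains the package end to end on generated data: simulate a plate,
#' batch-correct the stains, QC and featurize the traces, fit the forward
#' models (time-series and featurized linear, optionally the CNN), fit the
#' reverse multiple regressions for every dynamic feature, train the
#' signaling-history classifier at single-cell and regional level, and write
#' every table plus a JSON report to `output_dir`.
#'
#' @param config An `erk_config` (see [default_config()], [load_config()]).
#' @param output_dir Directory for the result tables; created if missing.
#'   `NULL` skips writing.
#' @return List of class `erk_report` with all fitted objects and a
#'   `summary` tibble (invisibly returns the same when writing).
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL) {
  stage <- function(name, expr) {
    if (isTRUE(config$output$verbose)) message("[", name, "]")
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("stage `%s` failed: %s", name,
                           conditionMessage(e)))
    })
  }
  cfg_hash <- rlang::hash(unclass(config))

  layout <- stage("layout", default_layout(
    n_cells = config$layout$n_cells, replicates = config$layout$replicates,
    field_um = config$layout$field_um))
  dataset <- stage("simulate", simulate_plate(
    layout, sim_config(noise_cv = config$generator$noise_cv,
                       batch_sdlog10 = config$generator$batch_sdlog10),
    seed = config$seed))

  bc <- stage("batch_correct", batch_correct(
    dataset$stains, reference = dataset$truth$reference_replicate))
  stains <- bc$corrected

  traces <- stage("qc", qc_traces(dataset$traces,
                                  min_hours = config$qc$min_hours))
  feats <- stage("featurize", erk_features(
    traces, min_prominence = default_prominence(
      traces, config$features$prominence_fraction)))

  splits <- stage("splits", make_splits(dataset$cells,
                                        n_folds = config$forward$n_folds,
                                        seed = config$seed))
  target <- setNames(log10(stains$Fra1), stains$cell_id)
  forward <- stage("forward", {
    out <- list(ts_linear = fit_ts_linear(traces, target, splits),
                feat_linear = fit_featurized_linear(feats, target, splits))
    if (isTRUE(config$forward$cnn)) {
      out$cnn <- fit_erk_cnn(traces, target, splits,
                             config = train_config(
                               epochs = config$forward$epochs,
                               seed = config$seed))
    }
    out
  })

  reverse <- stage("reverse", purrr::map(
    setNames(nm = ERK_FEATURES),
    ~ fit_reverse_mlr(stains, feats, .x, folds = config$reverse$folds,
                      seed = config$seed)))

  classifier <- stage("classify", {
    proto <- cluster_prototypes(traces, k = config$classifier$k,
                                seed = config$seed)
    keep <- filter_prototype_members(proto, config$classifier$r_min)
    clf <- fit_history_classifier(
      stains, proto$labels[keep, c("cell_id", "class")],
      n_rounds = config$classifier$n_rounds,
      folds = config$classifier$folds, seed = config$seed)
    regional <- regional_pipeline(
      list(traces = traces, cells = dataset$cells, stains = stains),
      radius_um = config$classifier$radius_um, k = config$classifier$k,
      seed = config$seed, r_min = config$classifier$r_min,
      n_rounds = config$classifier$n_rounds)
    overlay <- annotate_histories(clf, stains, dataset$cells)
    list(prototypes = proto, single_cell = clf, regional = regional,
         overlay = overlay)
  })

  summary <- tibble::tibble(
    quantity = c("n_cells", "n_qc_cells",
                 "forward_ts_linear_test_r2", "forward_feat_linear_test_r2",
                 if (isTRUE(config$forward$cnn)) "forward_cnn_test_r2",
                 "reverse_mean_r2", "classifier_accuracy",
                 "regional_accuracy"),
    value = c(nrow(dataset$cells), length(unique(traces$cell_id)),
              mean(dplyr::filter(forward$ts_linear$metrics,
                                 .data$split == "test")$r2),
              mean(dplyr::filter(forward$feat_linear$metrics,
                                 .data$split == "test")$r2),
              if (isTRUE(config$forward$cnn))
                mean(dplyr::filter(forward$cnn$metrics,
                                   .data$split == "test")$r2),
              reverse$mean$r2, classifier$single_cell$accuracy,
              classifier$regional$classifier$accuracy))

  report <- structure(list(
    dataset = dataset, stains = stains, batch_scalings = bc$scalings,
    features = feats, forward = forward, reverse = reverse,
    classifier = classifier, summary = summary, config = config,
    config_hash = cfg_hash), class = "erk_report")

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      p <- file.path(output_dir, name)
      con <- file(p, "w")
      writeLines(sprintf("# erkhistory pipeline output; config_hash=%s",
                         cfg_hash), con)
      write.csv(df, con, row.names = FALSE)
      close(con)
    }
    wr(dataset$traces, "traces.csv")
    wr(dataset$cells, "cells.csv")
    wr(stains, "stains.csv")
    wr(feats, "features.csv")
    wr(classifier$overlay, "overlay.csv")
    wr(summary, "summary.csv")
    jsonlite::write_json(
      list(config = unclass(config), config_hash = cfg_hash,
           summary = setNames(as.list(summary$value), summary$quantity)),
      file.path(output_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(report)
}

#' @export
print.erk_report <- function(x, ...) {
  cat("erkhistory pipeline report (config", substr(x$config_hash, 1, 8),
      ")\n")
  print(x$summary)
  invisible(x)
}
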