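#' Treatment specification for one well
#'
#' @param egf_dose EGF concentration in ng/ml (0 = control).
#' @param egf_time_min Minutes from experiment start at which EGF is added.
#' @param meki_time_min Minutes at which MEK inhibitor (100 nM PD0325901
#'   analog) is added, or `NA` for none.
#' @param label Condition label; defaults to a composed string.
#' @return One-row tibble.
#' @export
treatment_spec <- function(egf_dose = 20, egf_time_min = 0,
                           meki_time_min = NA_real_, label = NULL) {
  abort_if(egf_dose < 0, "`egf_dose` must be >= 0")
  abort_if(egf_time_min < 0, "`egf_time_min` must be >= 0")
  abort_if(!is.na(meki_time_min) && meki_time_min < 0,
           "`meki_time_min` must be >= 0")
  label <- label %||% sprintf("egf%g_t%g%s", egf_dose, egf_time_min,
                              if (is.na(meki_time_min)) ""
                              else sprintf("_meki%g", meki_time_min))
  tibble::tibble(egf_dose = egf_dose, egf_time_min = egf_time_min,
                 meki_time_min = meki_time_min, label = label)
}

#' Plate layout for a synthetic experiment
#'
#' @param wells Tibble with one row per (well, replicate): columns `well`,
#'   `replicate`, `n_cells`, a treatment (columns of [treatment_spec()]) and
#'   optionally `class_id` (the ground-truth signaling-history archetype).
#' @param field_um Imaging field size `c(width, height)` in micrometers;
#'   default 702 x 785.
#' @return List of class `plate_layout`.
#' @export
plate_layout <- function(wells, field_um = c(702, 785)) {
  abort_if(any(field_um <= 0), "field dimensions must be positive")
  abort_if(anyDuplicated(wells$well) > 0, "well ids must be unique")
  abort_if(any(wells$n_cells < 1), "each well needs n_cells >= 1")
  if (is.null(wells$class_id)) wells$class_id <- NA_integer_
  structure(list(wells = wells, field_um = field_um), class = "plate_layout")
}

#' Default five-archetype layout
#'
#' One well per signaling-history archetype and replicate, mirroring the
#' treatment regimes that produce the five canonical history classes:
#' moderate activity switched off mid-experiment (EGF then MEK inhibitor at
#' 12 h), consistently low (control), recent activation (EGF in the final
#' 3 h), mid-term activation (EGF at 10 h), and sustained high activity
#' (EGF from the start).
#'
#' @param n_cells Cells per well.
#' @param replicates Number of experimental replicates.
#' @param field_um Field size in micrometers.
#' @return A `plate_layout`.
#' @export
default_layout <- function(n_cells = 60, replicates = 3,
                           field_um = c(702, 785)) {
  arch <- dplyr::bind_rows(
    treatment_spec(20, 0, 720, "egf_meki12h"),
    treatment_spec(0, 0, NA, "control"),
    treatment_spec(20, 960, NA, "egf_recent"),
    treatment_spec(20, 600, NA, "egf_midterm"),
    treatment_spec(20, 0, NA, "egf_sustained"))
  arch$class_id <- 1:5
  wells <- purrr::map_dfr(seq_len(replicates), function(r) {
    w <- arch
    w$replicate <- r
    w$well <- sprintf("W%d_%d", r, seq_len(nrow(arch)))
    w$n_cells <- n_cells
    w
  })
  plate_layout(wells, field_um)
}

#' Dose-series layout
#'
#' A well per EGF dose (plus control) per replicate, all stimulated at the
#' same time — the matched-condition design used to anchor replicate batch
#' correction and to test dose response.
#'
#' @param doses EGF doses in ng/ml.
#' @param n_cells Cells per well.
#' @param replicates Number of replicates.
#' @param egf_time_min Stimulation time.
#' @param field_um Field size.
#' @return A `plate_layout`.
#' @export
dose_series_layout <- function(doses = c(0, 0.1, 0.5, 2.5, 10, 20),
                               n_cells = 50, replicates = 3,
                               egf_time_min = 30, field_um = c(702, 785)) {
  wells <- purrr::map_dfr(seq_len(replicates), function(r) {
    w <- purrr::map_dfr(doses, function(d) {
      treatment_spec(d, if (d > 0) egf_time_min else 0, NA,
                     sprintf("egf%g", d))
    })
    w$class_id <- NA_integer_
    w$replicate <- r
    w$well <- sprintf("W%d_%d", r, seq_along(doses))
    w$n_cells <- n_cells
    w
  })
  plate_layout(wells, field_um)
}

#' Generator settings for synthetic traces and stains
#'
#' Defaults encode the study conditions the generator emulates: 190 samples
#' at 6-minute spacing (18.9 h), a low unstimulated baseline with
#' Ornstein-Uhlenbeck jitter, saturating EGF dose response with a fast
#' initial transient, partial adaptation of the sustained component,
#' dose-dependent stochastic pulsing with per-cell lognormal heterogeneity,
#' rapid exponential shutdown after MEK inhibition, spatially clustered
#' synchronized activity bursts in the final two hours, multiplicative
#' lognormal stain noise, and per-replicate per-target batch scale factors.
#'
#' @param n_timepoints,dt_min Samples per trace and sampling interval (min).
#' @param baseline,floor Unstimulated activity level and fully inhibited
#'   level.
#' @param ou_sd,ou_tau_min Stationary SD and relaxation time of the baseline
#'   jitter.
#' @param hill_k Dose (ng/ml) of half-maximal response.
#' @param sustained_amp,transient_amp Amplitudes of the sustained component
#'   and the extra initial transient at saturating dose.
#' @param media_amp,media_tau_min Amplitude and decay time of the small ERK
#'   transient triggered by the media change at the start of imaging, shared
#'   by every cell regardless of treatment (imaging begins shortly after a
#'   media change, which transiently activates the pathway).
#' @param adapt_floor,adapt_tau_min Long-run fraction of the sustained
#'   component and adaptation time constant.
#' @param transient_tau_min Decay time of the initial transient.
#' @param pulse_rate_h Pulse rate (per hour) at saturating dose.
#' @param pulse_amp,pulse_amp_sdlog Median and lognormal spread of pulse
#'   amplitudes.
#' @param pulse_width_min,pulse_width_sdlog Median and spread of pulse
#'   widths (Gaussian SD, minutes).
#' @param cell_amp_sdlog,cell_rate_sdlog Per-cell lognormal heterogeneity of
#'   response amplitude and pulse rate.
#' @param meki_tau_min Time constant of the post-inhibitor decay.
#' @param cluster_fraction Fraction of cells grouped into burst clusters.
#' @param cluster_size Inclusive size range of a burst cluster.
#' @param cluster_sd_um Spatial SD of cluster members around their center.
#' @param burst_amp,burst_sd_min Amplitude and temporal SD of the shared
#'   late burst.
#' @param burst_window_min Window (minutes before the end) in which burst
#'   centers fall.
#' @param noise_cv Coefficient of variation of multiplicative stain noise.
#' @param batch_sdlog10 SD (log10) of random per-replicate per-target batch
#'   factors; the reference replicate always has factor 1.
#' @return Named list of settings.
#' @export
sim_config <- function(n_timepoints = 190, dt_min = 6, baseline = 0.15,
                       floor = 0.03, ou_sd = 0.02, ou_tau_min = 30,
                       hill_k = 1, sustained_amp = 0.9, transient_amp = 0.5,
                       media_amp = 0.2, media_tau_min = 90,
                       adapt_floor = 0.55, adapt_tau_min = 300,
                       transient_tau_min = 90, pulse_rate_h = 0.5,
                       pulse_amp = 0.35, pulse_amp_sdlog = 0.4,
                       pulse_width_min = 12, pulse_width_sdlog = 0.3,
                       cell_amp_sdlog = 0.25, cell_rate_sdlog = 0.3,
                       meki_tau_min = 6, cluster_fraction = 0.2,
                       cluster_size = c(5, 30), cluster_sd_um = 25,
                       burst_amp = 0.7, burst_sd_min = 18,
                       burst_window_min = c(120, 40), noise_cv = 0.1,
                       batch_sdlog10 = 0.1) {
  abort_if(dt_min <= 0, "`dt_min` must be positive")
  as.list(environment())
}

# One cell's trace given its treatment and per-cell draws.  Uses the current
# RNG stream; callers wrap in with_seed().
simulate_trace_one <- function(treatment, config, burst_center = NA) {
  cfg <- config
  t <- seq(0, by = cfg$dt_min, length.out = cfg$n_timepoints)
  horizon <- max(t)
  te <- treatment$egf_time_min
  tm <- treatment$meki_time_min
  abort_if(!is.na(tm) && tm < 0, "MEKi before t = 0")

  # baseline with OU jitter
  a <- exp(-cfg$dt_min / cfg$ou_tau_min)
  ou <- numeric(length(t))
  ou[1] <- rnorm(1, 0, cfg$ou_sd)
  innov <- rnorm(length(t) - 1, 0, cfg$ou_sd * sqrt(1 - a^2))
  for (i in seq_along(innov)) ou[i + 1] <- a * ou[i] + innov[i]

  hill <- treatment$egf_dose / (treatment$egf_dose + cfg$hill_k)
  amp_f <- rlnorm(1, 0, cfg$cell_amp_sdlog)
  rate_f <- rlnorm(1, 0, cfg$cell_rate_sdlog)

  # media-change transient at the start of imaging, shared by all cells
  signal <- cfg$media_amp * rlnorm(1, 0, 0.2) * exp(-t / cfg$media_tau_min)
  if (hill > 0) {
    on <- t >= te
    dt_on <- t[on] - te
    signal[on] <- hill * amp_f *
      (cfg$sustained_amp * (cfg$adapt_floor + (1 - cfg$adapt_floor) *
                              exp(-dt_on / cfg$adapt_tau_min)) +
         cfg$transient_amp * exp(-dt_on / cfg$transient_tau_min))
    # stochastic pulse train on top of the sustained response
    window_end <- if (is.na(tm)) horizon else min(tm, horizon)
    window_h <- max(window_end - te, 0) / 60
    n_pulse <- rpois(1, cfg$pulse_rate_h * hill * rate_f * window_h)
    if (n_pulse > 0) {
      centers <- runif(n_pulse, te, window_end)
      amps <- rlnorm(n_pulse, log(cfg$pulse_amp), cfg$pulse_amp_sdlog) * amp_f
      widths <- rlnorm(n_pulse, log(cfg$pulse_width_min),
                       cfg$pulse_width_sdlog)
      for (p in seq_len(n_pulse)) {
        signal <- signal + amps[p] * exp(-(t - centers[p])^2 / (2 * widths[p]^2))
      }
    }
  }
  if (!is.na(burst_center)) {
    signal <- signal + cfg$burst_amp * rlnorm(1, 0, 0.15) *
      exp(-(t - burst_center)^2 / (2 * cfg$burst_sd_min^2))
  }

  base <- rep(cfg$baseline, length(t))
  if (!is.na(tm)) {
    inh <- ifelse(t < tm, 1, exp(-(t - tm) / cfg$meki_tau_min))
    base <- cfg$floor + (cfg$baseline - cfg$floor) * inh
    signal <- signal * inh
  }
  pmax(base + signal + ou, 0)
}

#' Simulate one ERK activity trace
#'
#' Generates a single cell's calibrated activity time series under a
#' treatment: baseline Ornstein-Uhlenbeck jitter, a dose-scaled saturating
#' response with initial transient and partial adaptation, a Poisson pulse
#' train with per-cell lognormal amplitude/rate heterogeneity, and — when a
#' MEK inhibitor time is set — exponential relaxation to the inhibited floor
#' (default time constant 6 min).
#'
#' @param treatment One-row tibble from [treatment_spec()].
#' @param config Settings from [sim_config()].
#' @param seed RNG seed.
#' @param burst_center Optional center time (min) of an injected late burst.
#' @return Tibble: `t_min`, `activity`.
#' @export
simulate_trace <- function(treatment, config = sim_config(), seed = 1,
                           burst_center = NA) {
  with_seed(seed, {
    act <- simulate_trace_one(treatment, config, burst_center)
    tibble::tibble(
      t_min = seq(0, by = config$dt_min, length.out = config$n_timepoints),
      activity = act)
  })
}

#' Assign spatial coordinates and burst clusters
#'
#' Places cells in the imaging field. A configurable fraction is grouped into
#' spatial clusters of 5-30 neighboring cells (members scattered around a
#' shared center); each cluster is assigned a synchronized late-window
#' activity burst time that [simulate_plate()] injects into its members'
#' traces. Remaining cells are uniform over the field.
#'
#' @param n_cells Number of cells (>= 1).
#' @param field_um Field `c(width, height)` in micrometers.
#' @param config Settings from [sim_config()].
#' @param seed RNG seed (omit when already inside a seeded context).
#' @return Tibble: `x_um`, `y_um`, `burst_cluster` (integer or `NA`),
#'   `burst_center_min`.
#' @export
assign_coordinates <- function(n_cells, field_um = c(702, 785),
                               config = sim_config(), seed = NULL) {
  abort_if(n_cells < 1, "`n_cells` must be >= 1")
  abort_if(any(field_um <= 0), "field dimensions must be positive")
  with_seed(seed, {
    cfg <- config
    horizon <- (cfg$n_timepoints - 1) * cfg$dt_min
    out <- tibble::tibble(
      x_um = runif(n_cells, 0, field_um[1]),
      y_um = runif(n_cells, 0, field_um[2]),
      burst_cluster = NA_integer_, burst_center_min = NA_real_)
    n_clustered_target <- floor(cfg$cluster_fraction * n_cells)
    cl <- 0L
    placed <- 0L
    pool <- sample.int(n_cells)  # cells eligible for clustering, random order
    while (placed + cfg$cluster_size[1] <= n_clustered_target) {
      cl <- cl + 1L
      size <- sample(cfg$cluster_size[1]:cfg$cluster_size[2], 1)
      size <- min(size, n_clustered_target - placed)
      if (size < cfg$cluster_size[1]) break
      members <- pool[(placed + 1):(placed + size)]
      placed <- placed + size
      cx <- runif(1, 0, field_um[1]); cy <- runif(1, 0, field_um[2])
      out$x_um[members] <- pmin(pmax(rnorm(size, cx, cfg$cluster_sd_um), 0),
                                field_um[1])
      out$y_um[members] <- pmin(pmax(rnorm(size, cy, cfg$cluster_sd_um), 0),
                                field_um[2])
      out$burst_cluster[members] <- cl
      out$burst_center_min[members] <- runif(
        1, horizon - cfg$burst_window_min[1], horizon - cfg$burst_window_min[2])
    }
    out
  })
}

#' Default gene parameterizations behind the synthetic stain panel
#'
#' Eight parameter sets of the delay-ODE model chosen to span the qualitative
#' behaviors of the canonical target panel: slow integrators whose endpoint
#' reflects cumulative activity (Fra1-like, pRb-like), intermediate
#' responders (cMyc, cFos, pcFos), fast-degrading recent-activity reporters
#' (Egr1-like, pERK-like), and an ERK-independent control (cJun-like, purely
#' basal transcription). These are illustrative defaults, not fitted values.
#'
#' @return `sim_etg_params` tibble with 8 rows, gene ids matching the panel
#'   target names.
#' @export
panel_genes <- function() {
  rows <- dplyr::bind_rows(
    sim_etg_params(0.10, k_dm = 0.002, k_dp = 0.002, k_dpp = 0.002,
                   k_deph = 0.02, gene_id = "Fra1"),
    sim_etg_params(0.05, k_dm = 0.040, k_dp = 0.060, k_dpp = 0.040,
                   k_deph = 0.02, gene_id = "Egr1"),
    sim_etg_params(0.10, k_dm = 0.020, k_dp = 0.030, k_dpp = 0.020,
                   k_deph = 0.02, gene_id = "cFos"),
    sim_etg_params(0.10, k_dm = 0.020, k_dp = 0.050, k_dpp = 0.030,
                   k_deph = 0.01, k_pp = 0.1, gene_id = "pcFos"),
    sim_etg_params(0.20, k_dm = 0.010, k_dp = 0.010, k_dpp = 0.010,
                   k_deph = 0.02, gene_id = "cMyc"),
    sim_etg_params(1.00, k_dm = 0.010, k_dp = 0.010, k_dpp = 0.010,
                   k_deph = 0.02, gene_id = "cJun"),
    sim_etg_params(0.05, k_dm = 0.080, k_dp = 0.100, k_dpp = 0.080,
                   k_deph = 0.02, gene_id = "pERK"),
    sim_etg_params(0.30, k_dm = 0.003, k_dp = 0.0015, k_dpp = 0.002,
                   k_deph = 0.02, gene_id = "pRb"))
  class(rows) <- c("sim_etg_params", class(tibble::tibble()))
  rows
}

#' Generate a synthetic endpoint stain panel from activity traces
#'
#' Runs each panel gene's delay-ODE response to every trace and reads out the
#' endpoint total protein, then applies multiplicative lognormal measurement
#' noise (mean 1, CV `noise_cv`) and the per-replicate per-target batch
#' factor. The noiseless endpoints are returned alongside as ground truth.
#'
#' @param traces Long trace table.
#' @param cells Cell table with `cell_id` and `replicate` (and any metadata
#'   to carry through: `condition`, `well`).
#' @param genes `sim_etg_params` table; gene ids become stain column names.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param batch_factors Tibble (`replicate`, `target`, `factor`), positive;
#'   default all 1.
#' @param seed RNG seed.
#' @return List: `stains` (wide tibble), `endpoints` (noiseless gene x cell
#'   matrix), `batch_factors`.
#' @export
simulate_stain_panel <- function(traces, cells, genes = panel_genes(),
                                 noise_cv = 0.1, batch_factors = NULL,
                                 seed = 1) {
  abort_if(nrow(genes) == 0, "gene list is empty")
  abort_if(noise_cv < 0, "`noise_cv` must be >= 0")
  ends <- run_etg_survey(genes, traces)
  cells <- cells[match(colnames(ends), cells$cell_id), ]
  if (is.null(batch_factors)) {
    batch_factors <- tidyr::expand_grid(replicate = unique(cells$replicate),
                                        target = genes$gene_id)
    batch_factors$factor <- 1
  }
  abort_if(any(batch_factors$factor <= 0), "batch factors must be positive")
  with_seed(seed, {
    sdlog <- sqrt(log(1 + noise_cv^2))
    meta <- intersect(c("cell_id", "well", "condition", "replicate"),
                      names(cells))
    stains <- cells[, meta]
    for (g in genes$gene_id) {
      fac <- batch_factors$factor[match(
        paste(cells$replicate, g),
        paste(batch_factors$replicate, batch_factors$target))]
      fac[is.na(fac)] <- 1
      noise <- if (noise_cv > 0) {
        rlnorm(ncol(ends), -sdlog^2 / 2, sdlog)
      } else rep(1, ncol(ends))
      stains[[g]] <- unname(ends[g, ] * noise * fac)
    }
    list(stains = stains, endpoints = ends, batch_factors = batch_factors)
  })
}

#' Generate a full synthetic dataset
#'
#' Drives the whole generator: per-cell traces under each well's treatment,
#' spatial coordinates with burst clusters (synchronized late bursts injected
#' into clustered cells' traces), an ODE-derived stain panel with
#' multiplicative noise and replicate batch factors, and a lossless ground
#' truth table. Every cell appears exactly once in each table.
#'
#' @param layout A [plate_layout()].
#' @param config Settings from [sim_config()].
#' @param seed RNG seed; the same seed and configuration reproduce the
#'   dataset exactly.
#' @param genes Panel gene parameterizations.
#' @param panel Generate the ODE-derived stain panel (default `TRUE`); set
#'   `FALSE` for trace-only studies, which skips the gene simulations.
#' @return List of class `erk_dataset`: `traces`, `cells`, `stains`, `truth`
#'   (list: `cells`, `batch_factors`, `endpoints`, `genes`), `config`.
#' @export
simulate_plate <- function(layout, config = sim_config(), seed = 1,
                           genes = panel_genes(), panel = TRUE) {
  abort_if(!inherits(layout, "plate_layout"), "`layout` must be a plate_layout")
  wells <- layout$wells
  abort_if(length(unique(wells$replicate)) < 1, "replicate count < 1")
  with_seed(seed, {
    cells_list <- list()
    traces_list <- list()
    offset <- 0L
    for (w in seq_len(nrow(wells))) {
      wrow <- wells[w, ]
      coords <- assign_coordinates(wrow$n_cells, layout$field_um, config)
      ids <- sprintf("c%05d", offset + seq_len(wrow$n_cells))
      offset <- offset + wrow$n_cells
      cells_list[[w]] <- tibble::tibble(
        cell_id = ids, well = wrow$well, condition = wrow$label,
        replicate = wrow$replicate, true_class = wrow$class_id,
        x_um = coords$x_um, y_um = coords$y_um,
        burst_cluster = ifelse(is.na(coords$burst_cluster), NA_integer_,
                               coords$burst_cluster + 1000L * w))
      traces_list[[w]] <- purrr::map_dfr(seq_len(wrow$n_cells), function(i) {
        tibble::tibble(
          cell_id = ids[i],
          t_min = seq(0, by = config$dt_min,
                      length.out = config$n_timepoints),
          activity = simulate_trace_one(wrow, config,
                                        coords$burst_center_min[i]))
      })
    }
    cells <- dplyr::bind_rows(cells_list)
    traces <- dplyr::bind_rows(traces_list)

    # replicate batch factors (reference = highest replicate id, factor 1)
    reps <- sort(unique(cells$replicate))
    reference <- max(reps)
    batch_factors <- tidyr::expand_grid(replicate = reps,
                                        target = genes$gene_id)
    batch_factors$factor <- ifelse(
      batch_factors$replicate == reference, 1,
      10^rnorm(nrow(batch_factors), 0, config$batch_sdlog10))

    pnl <- if (panel) {
      simulate_stain_panel(traces, cells, genes, noise_cv = config$noise_cv,
                           batch_factors = batch_factors,
                           seed = sample.int(.Machine$integer.max, 1))
    } else {
      list(stains = NULL, endpoints = NULL)
    }

    structure(list(
      traces = traces,
      cells = cells,
      stains = pnl$stains,
      truth = list(cells = cells[, c("cell_id", "true_class",
                                     "burst_cluster")],
                   batch_factors = batch_factors,
                   endpoints = pnl$endpoints, genes = genes,
                   reference_replicate = reference),
      config = config), class = "erk_dataset")
  })
}

#' @export
print.erk_dataset <- function(x, ...) {
  cat("Synthetic ERK dataset:", nrow(x$cells), "cells,",
      length(unique(x$cells$well)), "wells,",
      length(unique(x$cells$replicate)), "replicates\n")
  invisible(x)
}

#' Remove conditions from a dataset
#'
#' Drops every cell whose condition satisfies `predicate` from all tables of
#' the dataset consistently (traces, cells, stains, truth).
#'
#' @param dataset An `erk_dataset`.
#' @param predicate Function of the condition label vector returning logical
#'   `TRUE` for conditions to exclude.
#' @return The filtered `erk_dataset`.
#' @export
exclude_conditions <- function(dataset, predicate) {
  drop <- predicate(dataset$cells$condition)
  abort_if(all(drop), "predicate removes all cells")
  keep_ids <- dataset$cells$cell_id[!drop]
  dataset$cells <- dataset$cells[!drop, ]
  dataset$traces <- dataset$traces[dataset$traces$cell_id %in% keep_ids, ]
  dataset$stains <- dataset$stains[dataset$stains$cell_id %in% keep_ids, ]
  dataset$truth$cells <- dataset$truth$cells[
    dataset$truth$cells$cell_id %in% keep_ids, ]
  dataset$truth$endpoints <- dataset$truth$endpoints[
    , colnames(dataset$truth$endpoints) %in% keep_ids, drop = FALSE]
  dataset
}
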