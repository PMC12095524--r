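#' Quality-control filter for activity traces
#'
#' Drops cells tracked for less than `min_hours` and cells with any
#' non-finite sample or any sample outside the plausibility `bounds`
#' (calibrated activity is non-negative by construction, so the default lower
#' bound is 0).
#'
#' @param traces Long trace table (`cell_id`, `t_min`, `activity`).
#' @param min_hours Minimum tracked duration in hours (default 15).
#' @param bounds Length-2 numeric; samples outside drop the whole cell.
#' @return Filtered trace table containing only retained cells.
#' @export
qc_traces <- function(traces, min_hours = 15, bounds = c(0, Inf)) {
  abort_if(nrow(traces) == 0, "empty trace table")
  keep <- traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      span_h = (max(.data$t_min) - min(.data$t_min)) / 60,
      ok = all(is.finite(.data$activity)) &&
        all(.data$activity >= bounds[1] & .data$activity <= bounds[2]),
      .groups = "drop") |>
    dplyr::filter(.data$span_h >= min_hours, .data$ok)
  dplyr::semi_join(traces, keep, by = "cell_id")
}

#' Detect activity pulses by topographic prominence
#'
#' Finds interior strict local maxima and keeps those with prominence at
#' least `min_prominence`. Prominence is the standard topographic definition:
#' the drop from the peak to the higher of the two minima separating it from
#' the nearest higher terrain (or the trace edge). Pulse width is measured at
#' half prominence by linear interpolation of the crossings on each side
#' (clamped at the trace edges when the trace never re-crosses).
#'
#' @param t_min Sample times (minutes, uniform spacing).
#' @param activity Activity values, same length.
#' @param min_prominence Minimum prominence to keep a peak.
#' @return Tibble with one row per peak: `peak_index`, `t_peak`, `height`,
#'   `prominence`, `width_min`. Peak indices are strictly increasing.
#' @export
find_pulses <- function(t_min, activity, min_prominence = 0) {
  n <- length(activity)
  abort_if(n < 3, "need at least 3 samples to detect peaks")
  check_uniform_sampling(t_min)
  cand <- which(activity[-c(1, n)] > activity[-c(n - 1, n)] &
                  activity[-c(1, n)] > activity[-c(1, 2)]) + 1L
  if (length(cand) == 0) {
    return(tibble::tibble(peak_index = integer(), t_peak = numeric(),
                          height = numeric(), prominence = numeric(),
                          width_min = numeric()))
  }
  prom <- vapply(cand, function(i) {
    left <- activity[seq_len(i - 1)]
    higher_l <- which(left > activity[i])
    lo_l <- min(activity[(if (length(higher_l)) max(higher_l) else 1):i])
    right <- activity[(i + 1):n]
    higher_r <- which(right > activity[i])
    hi_r <- if (length(higher_r)) i + min(higher_r) else n
    lo_r <- min(activity[i:hi_r])
    activity[i] - max(lo_l, lo_r)
  }, numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) == 0) {
    return(tibble::tibble(peak_index = integer(), t_peak = numeric(),
                          height = numeric(), prominence = numeric(),
                          width_min = numeric()))
  }
  width <- vapply(seq_along(cand), function(j) {
    i <- cand[j]
    ref <- activity[i] - prom[j] / 2
    tl <- t_min[1]
    for (m in seq(i - 1, 1)) {
      if (activity[m] <= ref) {
        w <- (activity[m + 1] - ref) / (activity[m + 1] - activity[m])
        tl <- t_min[m + 1] + w * (t_min[m] - t_min[m + 1])
        break
      }
    }
    tr <- t_min[n]
    for (m in seq(i + 1, n)) {
      if (activity[m] <= ref) {
        w <- (activity[m - 1] - ref) / (activity[m - 1] - activity[m])
        tr <- t_min[m - 1] + w * (t_min[m] - t_min[m - 1])
        break
      }
    }
    tr - tl
  }, numeric(1))
  tibble::tibble(peak_index = cand, t_peak = t_min[cand],
                 height = activity[cand], prominence = prom,
                 width_min = width)
}

#' Default pulse prominence threshold for a dataset
#'
#' A configurable fraction (default 10%) of the interquartile range of all
#' activity values in the dataset; a single threshold shared by all cells so
#' pulse counts are comparable across conditions.
#'
#' @param traces Long trace table.
#' @param fraction Fraction of the activity IQR (default 0.1).
#' @return Scalar threshold.
#' @export
default_prominence <- function(traces, fraction = 0.1) {
  fraction * diff(quantile(traces$activity, c(0.25, 0.75), names = FALSE))
}

featurize_one <- function(t_min, activity, min_prominence) {
  dt <- t_min[2] - t_min[1]
  peaks <- find_pulses(t_min, activity, min_prominence)
  np <- nrow(peaks)
  window <- max(t_min) - min(t_min)
  x <- activity - mean(activity)
  n <- length(x)
  # Hann-tapered periodogram, zero-padded 8x: the taper suppresses the
  # sidelobe energy that would bias the power-weighted mean toward high
  # frequencies, and the padding removes the coarse-bin discretization
  taper <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  xw <- (x - mean(x)) * taper
  npad <- 8 * n
  pw <- Mod(fft(c(xw, numeric(npad - n))))^2 / n
  kmax <- floor(npad / 2)
  pw <- pw[2:(kmax + 1)]
  freqs <- (1:kmax) / (npad * dt) * 60  # cycles per hour
  freq <- if (sum(pw) > 0) sum(freqs * pw) / sum(pw) else 0
  tibble::tibble(
    mean = mean(activity),
    max = max(activity),
    sum_duration = if (np) sum(peaks$width_min) else 0,
    avg_duration = if (np) sum(peaks$width_min) / np else 0,
    sum_peak_height = if (np) sum(peaks$height) else 0,
    avg_peak_height = if (np) sum(peaks$height) / np else 0,
    avg_derivative = mean(abs(diff(activity))) / dt,
    avg_interpulse_interval = if (np >= 2) mean(diff(peaks$t_peak)) else window,
    frequency = freq,
    n_peaks = np,
    interval_imputed = np < 2
  )
}

#' Nine-feature summary of ERK activity dynamics
#'
#' Computes, per cell: mean and max activity; summed and average pulse
#' duration (width at half prominence, minutes); summed and average pulse
#' height (activity at the peak); average absolute derivative (activity per
#' minute); average inter-pulse interval (minutes; cells with fewer than two
#' pulses receive the observation window as a defined upper bound, recorded
#' in `interval_imputed`); and the power-weighted mean frequency of the
#' one-sided periodogram of the mean-subtracted, Hann-tapered trace
#' (cycles/hour; the taper keeps the estimate accurate for slow
#' oscillations).
#' `sum = avg * n_peaks` holds exactly for the duration and height pairs.
#'
#' @param traces Long trace table (`cell_id`, `t_min`, `activity`).
#' @param min_prominence Pulse prominence threshold; default
#'   [default_prominence()] of the dataset.
#' @return Tibble: `cell_id`, the nine features (see [erk_feature_names()]),
#'   `n_peaks`, and `interval_imputed`.
#' @export
erk_features <- function(traces, min_prominence = NULL) {
  abort_if(nrow(traces) == 0, "empty trace table")
  min_prominence <- min_prominence %||% default_prominence(traces)
  traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::arrange(.data$t_min, .by_group = TRUE) |>
    dplyr::summarise(featurize_one(.data$t_min, .data$activity,
                                   min_prominence), .groups = "drop")
}

#' Per-timepoint correlation between stains and activity
#'
#' Pearson correlation, across cells, between each stain target and the
#' activity value at each timepoint. Timepoints (or targets) with zero
#' variance yield `NA`, not 0.
#'
#' @param stains Wide stain table (`cell_id` + target columns).
#' @param traces Long trace table sharing `cell_id`s with `stains`.
#' @param targets Stain columns to use; default all.
#' @param log10_stains Correlate log10 stain values (default `TRUE`, matching
#'   how stain intensities are modeled throughout).
#' @return Tibble: `target`, `t_min`, `r`.
#' @export
timepoint_correlation <- function(stains, traces, targets = NULL,
                                  log10_stains = TRUE) {
  targets <- targets %||% stain_targets(stains)
  m <- trace_matrix(traces)
  t_min <- attr(m, "t_min")
  shared <- intersect(rownames(m), stains$cell_id)
  abort_if(length(shared) < 3, "need at least 3 shared cells")
  m <- m[shared, , drop = FALSE]
  s <- stains[match(shared, stains$cell_id), targets, drop = FALSE]
  purrr::map_dfr(targets, function(tg) {
    y <- s[[tg]]
    if (log10_stains) y <- log10(y)
    r <- suppressWarnings(as.numeric(cor(m, y)))
    r[!is.finite(r)] <- NA_real_
    tibble::tibble(target = tg, t_min = t_min, r = r)
  })
}
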