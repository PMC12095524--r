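#' Associated fraction of the FRET reporter from channel intensities
#'
#' Converts donor/acceptor intensities into the fraction of biosensor
#' molecules in the high-FRET ("associated") conformation,
#' `f_A = 1 - (I_CFP / I_YFP) / R_P`, where `R_P` is the ratio of imaging
#' power between the two channels. Under measurement noise the result can
#' fall slightly outside `[0, 1]`; values are propagated as-is and any
#' clamping is left to the caller (see [fa_to_activity()]).
#'
#' @param i_cfp Donor (cyan) channel intensity, arbitrary units.
#' @param i_yfp Acceptor (yellow) channel intensity; must be positive.
#' @param r_p Channel power ratio; must be positive.
#' @return Numeric vector of associated fractions.
#' @examples
#' compute_fa(2, 4, 1) # 0.5
#' @export
compute_fa <- function(i_cfp, i_yfp, r_p) {
  abort_if(any(!is.finite(i_yfp)) || any(i_yfp <= 0),
           "`i_yfp` must be positive to form the FRET ratio")
  abort_if(!is.finite(r_p) || r_p <= 0, "`r_p` must be positive")
  1 - (i_cfp / i_yfp) / r_p
}

#' Construct biosensor calibration parameters
#'
#' @param k_au Associated fraction of the fully unphosphorylated reporter.
#' @param k_ap Associated fraction of the fully phosphorylated reporter.
#'   Must satisfy `0 <= k_au < k_ap <= 1`.
#' @param r_p Channel power ratio carried for convenience (optional).
#' @return An object of class `fret_calibration`.
#' @export
calibration_params <- function(k_au, k_ap, r_p = NULL) {
  abort_if(!is.finite(k_au) || !is.finite(k_ap) || k_au < 0 || k_ap > 1 ||
             k_au >= k_ap,
           "calibration requires 0 <= k_au < k_ap <= 1")
  structure(list(k_au = k_au, k_ap = k_ap, r_p = r_p, fit = NULL),
            class = "fret_calibration")
}

#' Fit the biosensor calibration line from phos-tag anchor points
#'
#' Each anchor condition provides the phosphorylated fraction of the reporter
#' `p` (from a phos-tag gel shift) and the mean associated fraction `f_A`
#' measured by imaging for the same condition. The calibration is the
#' ordinary least squares fit of the affine relation
#' `f_A = K_AU + (K_AP - K_AU) * p`, the unique line consistent with the
#' activity transform of [fa_to_activity()] at its endpoints (`p = 0` gives
#' `K_AU`, `p = 1` gives `K_AP`).
#'
#' @param points Data frame with columns `phospho_fraction` (in `[0, 1]`) and
#'   `mean_fa`.
#' @return A `fret_calibration` object with elements `k_au`, `k_ap` and the
#'   underlying `lm` fit.
#' @export
fit_fret_calibration <- function(points) {
  abort_if(!all(c("phospho_fraction", "mean_fa") %in% names(points)),
           "`points` needs columns phospho_fraction and mean_fa")
  p <- points$phospho_fraction
  abort_if(any(p < 0 | p > 1), "phospho_fraction must lie in [0, 1]")
  abort_if(length(unique(p)) < 2,
           "need at least 2 distinct phospho_fraction values to fit")
  fit <- lm(mean_fa ~ phospho_fraction, data = points)
  k_au <- unname(coef(fit)[1])
  k_ap <- unname(coef(fit)[1] + coef(fit)[2])
  abort_if(k_ap <= k_au,
           "invalid calibration: fitted K_AP <= K_AU (non-increasing line)")
  out <- calibration_params(max(k_au, 0), min(k_ap, 1))
  out$fit <- fit
  out
}

#' @export
print.fret_calibration <- function(x, ...) {
  cat("FRET biosensor calibration: K_AU =", signif(x$k_au, 4),
      ", K_AP =", signif(x$k_ap, 4), "\n")
  invisible(x)
}

#' Convert associated fraction to calibrated ERK activity
#'
#' Applies the saturating transform `x = (f_A - K_AU) / (K_AP - f_A)`, the
#' concentration ratio of active ERK to its competing phosphatase. Measured
#' `f_A` values outside `[K_AU, K_AP)` are produced by noise; by default they
#' are clamped to `[K_AU, K_AP - eps]` with `eps` a fraction (1e-6) of the
#' calibration span, and the `clamped` attribute records which values were
#' touched. With `clamp = FALSE`, out-of-range values are an error because
#' the transform is unbounded at `f_A = K_AP`.
#'
#' @param fa Numeric vector of associated fractions.
#' @param cal A `fret_calibration` object (or list with `k_au`, `k_ap`).
#' @param clamp Clamp out-of-range values (default `TRUE`).
#' @return Numeric vector of non-negative activities with a logical
#'   `clamped` attribute.
#' @seealso [activity_to_fa()] for the exact inverse.
#' @export
fa_to_activity <- function(fa, cal, clamp = TRUE) {
  k_au <- cal$k_au; k_ap <- cal$k_ap
  eps <- 1e-6 * (k_ap - k_au)
  clamped <- fa < k_au | fa >= k_ap
  if (clamp) {
    fa <- pmin(pmax(fa, k_au), k_ap - eps)
  } else {
    abort_if(any(clamped),
             "f_A outside [k_au, k_ap) and clamp = FALSE: activity undefined")
  }
  x <- (fa - k_au) / (k_ap - fa)
  attr(x, "clamped") <- clamped
  x
}

#' Convert ERK activity back to associated fraction
#'
#' Exact inverse of [fa_to_activity()]:
#' `f_A = (K_AU + x * K_AP) / (1 + x)`, mapping `x = 0` to `K_AU` and
#' approaching `K_AP` monotonically as `x` grows.
#'
#' @param x Non-negative activity values.
#' @inheritParams fa_to_activity
#' @return Numeric vector of associated fractions in `[K_AU, K_AP)`.
#' @export
activity_to_fa <- function(x, cal) {
  abort_if(any(x < 0), "activity must be non-negative")
  (cal$k_au + x * cal$k_ap) / (1 + x)
}

#' Batch-correct stain intensities across replicates
#'
#' Aligns each stain target across experimental replicates using conditions
#' measured in every replicate. Per target, the log10 medians of the matched
#' conditions in a source replicate are regressed onto those of the reference
#' replicate (`reference = beta1 * source + beta0`); the fitted affine map is
#' then applied to every single-cell log10 value of the source replicate and
#' exponentiated back to the linear scale. The reference replicate is
#' unchanged; correction is monotone within a replicate, so rank order is
#' preserved. Matching uses condition labels. When several cell lines are
#' plated in tandem, medians are pooled over lines per condition, so one
#' scaling per (target, replicate) is shared by all lines (line differences
#' are preserved). A target with no usable spread across the matched
#' conditions (e.g. one not regulated by the treatments) only identifies the
#' offset; such targets fall back to pure median alignment (`beta1 = 1`)
#' with a warning.
#'
#' @param stains Data frame with `cell_id`, `replicate`, `condition` and one
#'   positive numeric column per stain target.
#' @param reference Replicate id to align the others to.
#' @param matched_conditions Conditions present in all replicates to anchor
#'   the fit; default: every condition shared by all replicates.
#' @param targets Stain columns to correct; default: all non-metadata columns.
#' @return List with `corrected` (same shape as `stains`) and `scalings`
#'   (tibble: target, replicate, beta0, beta1).
#' @export
batch_correct <- function(stains, reference, matched_conditions = NULL,
                          targets = NULL) {
  targets <- targets %||% stain_targets(stains)
  abort_if(length(targets) == 0, "no stain target columns found")
  for (tg in targets) {
    abort_if(any(!is.finite(stains[[tg]]) | stains[[tg]] <= 0),
             sprintf("stain `%s` has non-positive values; correction is in log space", tg))
  }
  reps <- unique(stains$replicate)
  abort_if(!reference %in% reps, "`reference` is not a replicate in `stains`")
  if (is.null(matched_conditions)) {
    matched_conditions <- Reduce(intersect,
      lapply(reps, function(r) unique(stains$condition[stains$replicate == r])))
  }
  abort_if(length(matched_conditions) < 2,
           "need >= 2 matched conditions shared by all replicates")

  med <- stains |>
    dplyr::filter(.data$condition %in% matched_conditions) |>
    dplyr::group_by(.data$replicate, .data$condition) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(targets),
                                   ~ log10(median(.x))), .groups = "drop")

  corrected <- stains
  scalings <- list()
  for (src in setdiff(reps, reference)) {
    m_src <- med[med$replicate == src, ]
    m_ref <- med[med$replicate == reference, ]
    m_src <- m_src[match(m_ref$condition, m_src$condition), ]
    for (tg in targets) {
      fit <- lm(y ~ x, data = data.frame(x = m_src[[tg]], y = m_ref[[tg]]))
      b0 <- unname(coef(fit)[1]); b1 <- unname(coef(fit)[2])
      if (!is.finite(b1) || b1 <= 0) {
        # a target flat across the matched conditions identifies only the
        # offset; fall back to pure median alignment
        warning(sprintf(
          "no usable condition spread for `%s` (replicate %s); offset-only correction",
          tg, src))
        b1 <- 1
        b0 <- mean(m_ref[[tg]]) - mean(m_src[[tg]])
      }
      idx <- corrected$replicate == src
      corrected[[tg]][idx] <- 10^(b0 + b1 * log10(corrected[[tg]][idx]))
      scalings[[length(scalings) + 1]] <- tibble::tibble(
        target = tg, replicate = src, reference = reference,
        beta0 = b0, beta1 = b1)
    }
  }
  list(corrected = corrected, scalings = dplyr::bind_rows(scalings))
}
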