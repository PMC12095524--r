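PARAM_ORDER <- c("k_ptf", "k_dtf", "tf_total", "k_b", "k_m", "tau_m", "k_dm",
                 "K_D", "v", "k_p", "tau_p", "k_dp", "k_pp", "k_deph", "k_dpp")

#' Parameters of one hypothetical ERK target gene
#'
#' Rate constants of the delay-ODE gene expression model: ERK phosphorylates
#' a transcription factor (total `tf_total`, rates `k_ptf`/`k_dtf`); the
#' phosphorylated factor drives transcription (basal `k_b`, induced `k_m`,
#' delay `tau_m` minutes, mRNA decay `k_dm`) under negative feedback from the
#' total protein product (half-max `K_D`, Hill exponent `v`; `K_D = Inf`
#' disables feedback); mRNA is translated (`k_p`, delay `tau_p`) into protein
#' that ERK phosphorylates (`k_pp`), with dephosphorylation `k_deph` and
#' degradation of the two protein forms `k_dp` / `k_dpp`. All rates are per
#' minute. `k_b` and `k_m` are parameterized through `baseline_fraction =
#' k_b / (k_b + k_m)` with the total `k_txn = k_b + k_m` fixed, so fractional
#' expression at baseline is directly settable.
#'
#' @param baseline_fraction Fraction of transcription that is basal, in
#'   `[0, 1]`.
#' @param k_txn Total transcription rate `k_b + k_m` (concentration/min).
#' @param k_dm,k_dp,k_dpp,k_deph,K_D The "varied" parameters of a gene
#'   survey: mRNA decay, protein decay, phospho-protein decay, protein
#'   dephosphorylation and feedback half-max.
#' @param k_ptf,k_dtf,tf_total,tau_m,v,k_p,tau_p,k_pp Fixed parameters.
#' @param gene_id Optional identifier.
#' @return One-row tibble of class `sim_etg_params`.
#' @export
sim_etg_params <- function(baseline_fraction = 0.25, k_txn = 0.02,
                           k_dm = 0.01, k_dp = 0.01, k_dpp = 0.01,
                           k_deph = 0.02, K_D = Inf,
                           k_ptf = 0.1, k_dtf = 0.1, tf_total = 1,
                           tau_m = 15, v = 2, k_p = 0.02, tau_p = 15,
                           k_pp = 0.05, gene_id = "gene_1") {
  out <- tibble::tibble(
    gene_id = gene_id, k_ptf = k_ptf, k_dtf = k_dtf, tf_total = tf_total,
    k_b = baseline_fraction * k_txn, k_m = (1 - baseline_fraction) * k_txn,
    tau_m = tau_m, k_dm = k_dm, K_D = K_D, v = v, k_p = k_p, tau_p = tau_p,
    k_dp = k_dp, k_pp = k_pp, k_deph = k_deph, k_dpp = k_dpp,
    baseline_fraction = baseline_fraction)
  validate_etg_params(out)
  class(out) <- c("sim_etg_params", class(out))
  out
}

validate_etg_params <- function(params) {
  rates <- setdiff(PARAM_ORDER, "K_D")
  for (nm in rates) {
    abort_if(any(!is.finite(params[[nm]]) | params[[nm]] < 0),
             sprintf("parameter `%s` must be finite and >= 0", nm))
  }
  abort_if(any(params$K_D <= 0), "`K_D` must be positive (Inf = no feedback)")
  abort_if(any(params$tf_total <= 0), "`tf_total` must be positive")
  abort_if(any(params$v < 1), "Hill exponent `v` must be >= 1")
  invisible(params)
}

params_matrix <- function(params) {
  as.matrix(params[, PARAM_ORDER, drop = FALSE])
}

#' Default sampling ranges for the six varied gene parameters
#'
#' Log-uniform bounds spanning two orders of magnitude for the four decay /
#' dephosphorylation rates (half-lives from ~7 minutes to ~11.5 hours, the
#' range over which an endpoint readout moves from tracking recent activity
#' to integrating the whole recording), and for the feedback half-max around
#' the typical steady protein level. `baseline_fraction` is sampled uniformly
#' on `[0, 1]`.
#'
#' @return Named list of `c(low, high)` bounds.
#' @export
etg_param_ranges <- function() {
  list(k_dm = c(1e-3, 1e-1), k_dp = c(1e-3, 1e-1), k_dpp = c(1e-3, 1e-1),
       k_deph = c(1e-3, 1e-1), K_D = c(0.3, 30))
}

#' Sample hypothetical gene parameterizations
#'
#' Draws `n` genes: the five rate-like varied parameters log-uniform within
#' `ranges`, `baseline_fraction` uniform on `[0, 1]`, all other parameters at
#' the fixed defaults of [sim_etg_params()] (overridable through `...`).
#'
#' @param n Number of genes.
#' @param ranges Named list of `c(low, high)` bounds (positive, low < high);
#'   see [etg_param_ranges()].
#' @param seed RNG seed.
#' @param ... Fixed-parameter overrides passed to [sim_etg_params()].
#' @return `sim_etg_params` tibble with `n` rows.
#' @export
sample_etg_params <- function(n, ranges = etg_param_ranges(), seed = 1, ...) {
  for (nm in names(ranges)) {
    b <- ranges[[nm]]
    abort_if(length(b) != 2 || any(b <= 0) || b[1] >= b[2],
             sprintf("invalid bounds for `%s`", nm))
  }
  with_seed(seed, {
    draws <- lapply(ranges, function(b) exp(runif(n, log(b[1]), log(b[2]))))
    bf <- runif(n)
    rows <- purrr::map_dfr(seq_len(n), function(i) {
      sim_etg_params(baseline_fraction = bf[i], k_dm = draws$k_dm[i],
                     k_dp = draws$k_dp[i], k_dpp = draws$k_dpp[i],
                     k_deph = draws$k_deph[i], K_D = draws$K_D[i],
                     gene_id = sprintf("gene_%04d", i), ...)
    })
    class(rows) <- c("sim_etg_params", class(tibble::tibble()))
    rows
  })
}

#' Steady state of the gene model under constant ERK
#'
#' Without feedback (`K_D = Inf`) the fixed point is returned in closed form.
#' With feedback, the implied total protein is a decreasing function of the
#' assumed total, so the unique fixed point is found by bisection on
#' `[0, implied(0)]`. A parameter set with no finite steady state (e.g. zero
#' clearance with non-zero production) is an error, not a silent clamp.
#'
#' @param params One-row `sim_etg_params`.
#' @param erk_const Constant ERK activity level (>= 0).
#' @return Named numeric: `tfp`, `mrna`, `p`, `pp`.
#' @export
etg_steady_state <- function(params, erk_const) {
  abort_if(erk_const < 0, "`erk_const` must be >= 0")
  validate_etg_params(params)
  y <- simetg_steady_cpp(params_matrix(params)[1, ], erk_const)
  abort_if(any(!is.finite(y)), "no finite steady state for these parameters")
  setNames(as.numeric(y), c("tfp", "mrna", "p", "pp"))
}

# Interpolate a trace onto the half-step grid required by the integrator.
erk_half_grid <- function(t_min, activity, dt, n_steps) {
  tq <- seq(t_min[1], by = dt / 2, length.out = 2 * n_steps + 1)
  stats::approx(t_min, activity, xout = tq, rule = 2)$y
}

#' Simulate the gene response to one ERK activity trace
#'
#' Integrates the delay-ODE model with fixed-step RK4 (default `dt` 1 min);
#' delayed states are read from the stored solution with linear
#' interpolation, the pre-history equals the initial condition, and species
#' are floored at zero. The initial condition defaults to the steady state
#' under the trace's first activity value (the pre-stimulus level).
#'
#' @param params One-row `sim_etg_params`.
#' @param trace Data frame with `t_min` and `activity` for one cell.
#' @param dt Integration step in minutes; must divide the sampling interval.
#' @param y0 Optional initial state `c(tfp, mrna, p, pp)`.
#' @return Tibble: `t_min`, `tfp`, `mrna`, `p`, `pp`, plus a `readout`
#'   attribute (endpoint total protein `p + pp`).
#' @export
simulate_etg <- function(params, trace, dt = 1, y0 = NULL) {
  abort_if(dt <= 0, "`dt` must be positive")
  validate_etg_params(params)
  t_min <- trace$t_min
  interval <- check_uniform_sampling(t_min)
  abort_if(is.finite(interval) &&
             abs(interval / dt - round(interval / dt)) > 1e-9,
           "`dt` must divide the trace sampling interval")
  n_steps <- round((max(t_min) - min(t_min)) / dt)
  pm <- params_matrix(params)[1, ]
  if (is.null(y0)) {
    y0 <- simetg_steady_cpp(pm, trace$activity[1])
    abort_if(any(!is.finite(y0)),
             "no finite pre-stimulus steady state; supply `y0`")
  }
  erk_half <- erk_half_grid(t_min, trace$activity, dt, n_steps)
  grid <- simetg_integrate_cpp(pm, erk_half, y0, t_min[1], dt, n_steps)
  out <- tibble::tibble(
    t_min = seq(t_min[1], by = dt, length.out = n_steps + 1),
    tfp = grid[, 1], mrna = grid[, 2], p = grid[, 3], pp = grid[, 4])
  attr(out, "readout") <- out$p[nrow(out)] + out$pp[nrow(out)]
  out
}

#' Endpoint survey of many genes over many cells
#'
#' Simulates every gene against every cell's activity trace and returns the
#' endpoint readout — the simulated analog of a fixed-cell antibody
#' measurement taken when the recording ends.
#'
#' @param params `sim_etg_params` table (one row per gene).
#' @param traces Long trace table.
#' @param dt Integration step (minutes).
#' @param readout `"total"` for `p + pp` (total-protein antibody) or
#'   `"phospho"` for `pp` only.
#' @return Matrix `n_genes x n_cells` with gene/cell ids as dimnames.
#' @export
run_etg_survey <- function(params, traces, dt = 1,
                           readout = c("total", "phospho")) {
  readout <- match.arg(readout)
  validate_etg_params(params)
  m <- trace_matrix(traces)
  t_min <- attr(m, "t_min")
  n_steps <- round((max(t_min) - min(t_min)) / dt)
  erk_half <- apply(m, 1, function(a) erk_half_grid(t_min, a, dt, n_steps))
  ends <- simetg_survey_cpp(params_matrix(params), erk_half, m[, 1],
                            t_min[1], dt, n_steps,
                            as.integer(readout == "phospho"))
  abort_if(any(!is.finite(ends)),
           "simulation failed (no finite steady state) for some gene/cell")
  dimnames(ends) <- list(params$gene_id, rownames(m))
  ends
}

#' Direction of ERK regulation for a gene
#'
#' Compares the endpoint readout under a sustained high-ERK step against zero
#' ERK over a standard horizon. A gene whose product is channeled into a
#' fast-degrading phosphorylated form by ERK can be net negatively regulated
#' even though ERK drives its transcription.
#'
#' @param params `sim_etg_params` table.
#' @param erk_high Sustained high activity level (default 1).
#' @param horizon_min Simulation horizon (default 1134 min, the standard
#'   19-hour recording).
#' @param dt Integration step.
#' @param tol Ties within `tol` (relative) are labeled positive and flagged.
#' @return Tibble: `gene_id`, `sign` ("positive"/"negative"), `delta`,
#'   `degenerate`.
#' @export
regulation_sign <- function(params, erk_high = 1, horizon_min = 1134, dt = 1,
                            tol = 1e-9) {
  validate_etg_params(params)
  n <- horizon_min + 1
  traces <- tibble::tibble(
    cell_id = rep(c("hi", "lo"), each = n),
    t_min = rep(seq(0, horizon_min, by = 1), 2),
    activity = rep(c(erk_high, 0), each = n))
  ends <- run_etg_survey(params, traces, dt = dt)
  delta <- ends[, "hi"] - ends[, "lo"]
  scale <- pmax(abs(ends[, "hi"]), abs(ends[, "lo"]), 1e-300)
  degen <- abs(delta) / scale <= tol
  tibble::tibble(gene_id = params$gene_id,
                 sign = unname(ifelse(delta >= 0 | degen,
                                      "positive", "negative")),
                 delta = unname(delta), degenerate = unname(degen))
}

#' Screen gene endpoints for predictivity of ERK features
#'
#' For each (gene, feature) pair, the coefficient of determination of the
#' one-variable least-squares regression of the feature on the gene's
#' endpoint readout, plus the fraction of genes exceeding each R-squared
#' threshold per feature.
#'
#' @param endpoints Matrix from [run_etg_survey()] (genes x cells).
#' @param features Feature table from [erk_features()] covering the same
#'   cells.
#' @param thresholds R-squared thresholds to summarize (default 0.5, 0.8).
#' @return List: `r2` (tibble gene_id x feature x r2) and `fractions`
#'   (tibble feature x threshold x fraction).
#' @export
screen_predictivity <- function(endpoints, features,
                                thresholds = c(0.5, 0.8)) {
  cells <- intersect(colnames(endpoints), features$cell_id)
  abort_if(length(cells) < 10, "need at least 10 cells")
  E <- endpoints[, cells, drop = FALSE]
  Fm <- as.matrix(features[match(cells, features$cell_id), ERK_FEATURES])
  r2 <- purrr::map_dfr(seq_len(nrow(E)), function(g) {
    x <- E[g, ]
    vx <- var(x)
    r <- if (vx == 0) rep(NA_real_, ncol(Fm)) else {
      suppressWarnings(as.numeric(cor(x, Fm))^2)
    }
    r[!is.finite(r)] <- NA_real_
    tibble::tibble(gene_id = rownames(E)[g], feature = ERK_FEATURES, r2 = r)
  })
  fractions <- purrr::map_dfr(thresholds, function(th) {
    r2 |>
      dplyr::group_by(.data$feature) |>
      dplyr::summarise(threshold = th,
                       fraction = mean(.data$r2 > th, na.rm = TRUE),
                       .groups = "drop")
  })
  list(r2 = r2, fractions = fractions)
}

#' Per-timepoint correlation profile of gene endpoints
#'
#' Pearson correlation, across cells, between each gene's endpoint readout
#' and the activity at each timepoint — the simulated counterpart of the
#' stain/timepoint correlation map. Fast-degrading genes concentrate their
#' correlation in the final hours; slow integrators spread it broadly.
#'
#' @inheritParams screen_predictivity
#' @param traces Long trace table for the surveyed cells.
#' @return Tibble: `gene_id`, `t_min`, `r`.
#' @export
survey_timepoint_profile <- function(endpoints, traces) {
  m <- trace_matrix(traces)
  t_min <- attr(m, "t_min")
  cells <- intersect(colnames(endpoints), rownames(m))
  abort_if(length(cells) < 3, "need at least 3 shared cells")
  m <- m[cells, , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(endpoints)), function(g) {
    r <- suppressWarnings(as.numeric(cor(m, endpoints[g, cells])))
    r[!is.finite(r)] <- NA_real_
    tibble::tibble(gene_id = rownames(endpoints)[g], t_min = t_min, r = r)
  })
}
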