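const_trace <- function(level, n = 200, dt = 6) {
  tibble::tibble(cell_id = "c", t_min = seq(0, by = dt, length.out = n),
                 activity = level)
}

test_that("zero input with zero basal rate stays at the zero fixed point", {
  p <- sim_etg_params(baseline_fraction = 0, K_D = Inf)
  tr <- simulate_etg(p, const_trace(0), dt = 1)
  expect_true(all(as.matrix(tr[, c("tfp", "mrna", "p", "pp")]) == 0))
  ss <- etg_steady_state(p, 0)
  expect_true(all(ss == 0))
})

test_that("feedback-off steady state equals the closed form", {
  set.seed(31)
  for (i in 1:25) {
    p <- sim_etg_params(baseline_fraction = runif(1),
                        k_dm = exp(runif(1, log(1e-3), log(1e-1))),
                        k_dp = exp(runif(1, log(1e-3), log(1e-1))),
                        k_dpp = exp(runif(1, log(1e-3), log(1e-1))),
                        k_deph = exp(runif(1, log(1e-3), log(1e-1))),
                        K_D = Inf)
    erk <- runif(1, 0, 2)
    want <- steady_oracle(p, erk)
    got <- etg_steady_state(p, erk)
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
  }
})

test_that("with feedback the steady state satisfies the rate balance", {
  p <- sim_etg_params(K_D = 2, v = 2)
  ss <- etg_steady_state(p, 1)
  fb <- 1 / (((ss["p"] + ss["pp"]) / 2)^2 + 1)
  # mRNA balance at the fixed point
  expect_equal(unname((p$k_b + p$k_m * ss["tfp"]) * fb - p$k_dm * ss["mrna"]),
               0, tolerance = 1e-9)
  # simulation started at the steady state stays there
  tr <- simulate_etg(p, const_trace(1), dt = 1, y0 = as.numeric(ss))
  expect_equal(unname(as.numeric(tr[nrow(tr), c("tfp", "mrna", "p", "pp")])),
               unname(as.numeric(ss)), tolerance = 1e-6)
})

test_that("steady-state mRNA decreases in the mRNA degradation rate", {
  ks <- 10^seq(-3, -1, length.out = 10)
  m <- vapply(ks, function(k) {
    etg_steady_state(sim_etg_params(k_dm = k, K_D = Inf), 1)["mrna"]
  }, numeric(1))
  expect_true(all(diff(m) < 0))
})

test_that("species stay non-negative and TFP never exceeds the total", {
  set.seed(32)
  t <- seq(0, by = 6, length.out = 190)
  tr <- tibble::tibble(cell_id = "c", t_min = t,
                       activity = pmax(0, 0.2 + cumsum(rnorm(190, 0, 0.1))))
  p <- sim_etg_params(K_D = 1, k_pp = 0.2)
  out <- simulate_etg(p, tr, dt = 1)
  expect_true(all(as.matrix(out[, c("tfp", "mrna", "p", "pp")]) >= 0))
  expect_true(all(out$tfp <= p$tf_total + 1e-9))
})

test_that("protein mass is conserved without degradation or production", {
  p <- sim_etg_params(baseline_fraction = 0, k_txn = 0,
                      k_dm = 0.01, k_dp = 0, k_dpp = 0, K_D = Inf)
  out <- simulate_etg(p, const_trace(1.5, n = 120), dt = 1,
                      y0 = c(0, 0, 1, 0))
  expect_lt(max(abs(out$p + out$pp - 1)), 1e-9)
})

test_that("halving the step changes endpoints by < 0.1%", {
  set.seed(33)
  t <- seq(0, by = 6, length.out = 120)
  tr <- tibble::tibble(cell_id = "c", t_min = t,
                       activity = 0.3 + 0.5 * (t > 200) + 0.2 * sin(t / 40))
  for (i in 1:6) {
    p <- sample_etg_params(1, seed = i)
    a <- attr(simulate_etg(p, tr, dt = 1), "readout")
    b <- attr(simulate_etg(p, tr, dt = 0.5), "readout")
    expect_lt(abs(a - b) / max(abs(b), 1e-12), 1e-3)
  }
})

test_that("integration agrees with an independent DDE solver", {
  skip_if_not_installed("deSolve")
  p <- sim_etg_params(baseline_fraction = 0.2, k_dm = 0.02, k_dp = 0.01,
                      k_dpp = 0.03, k_deph = 0.02, K_D = 3)
  t <- seq(0, by = 6, length.out = 100)
  act <- 0.2 + 0.8 * (t > 120 & t < 420)
  erk_fun <- stats::approxfun(t, act, rule = 2)
  y0 <- as.numeric(etg_steady_state(p, act[1]))
  dede_rhs <- function(tt, y, parms) {
    lag_m <- if (tt > p$tau_m) deSolve::lagvalue(tt - p$tau_m) else y0
    lag_p <- if (tt > p$tau_p) deSolve::lagvalue(tt - p$tau_p) else y0
    e <- erk_fun(tt)
    fb <- 1 / (((lag_m[3] + lag_m[4]) / p$K_D)^p$v + 1)
    list(c(
      p$k_ptf * e * (p$tf_total - y[1]) - p$k_dtf * y[1],
      (p$k_b + p$k_m * lag_m[1]) * fb - p$k_dm * y[2],
      p$k_p * lag_p[2] + p$k_deph * y[4] - (p$k_dp + p$k_pp * e) * y[3],
      p$k_pp * e * y[3] - (p$k_dpp + p$k_deph) * y[4]))
  }
  ref <- deSolve::dede(y0, times = t, func = dede_rhs, parms = NULL)
  got <- simulate_etg(p, tibble::tibble(cell_id = "c", t_min = t,
                                        activity = act), dt = 1)
  got_at <- got[got$t_min %in% t, ]
  for (j in 1:4) {
    expect_equal(got_at[[j + 1]], unname(ref[, j + 1]), tolerance = 1e-3)
  }
})

test_that("parameter sampling respects bounds and the seed", {
  g <- sample_etg_params(1000, seed = 4)
  expect_identical(nrow(g), 1000L)
  rng <- etg_param_ranges()
  for (nm in names(rng)) {
    expect_true(all(g[[nm]] >= rng[[nm]][1] & g[[nm]] <= rng[[nm]][2]))
  }
  expect_true(all(g$baseline_fraction >= 0 & g$baseline_fraction <= 1))
  expect_equal(g$k_b + g$k_m, rep(0.02, 1000), tolerance = 1e-12)
  g2 <- sample_etg_params(1000, seed = 4)
  expect_identical(g, g2)
  expect_error(sample_etg_params(5, ranges = list(k_dm = c(2, 1))), "bounds")
})

test_that("survey endpoints line up with single simulations", {
  tr <- dplyr::bind_rows(
    dplyr::mutate(const_trace(0.2, 60), cell_id = "a"),
    dplyr::mutate(const_trace(1.0, 60), cell_id = "b"))
  g <- sample_etg_params(3, seed = 6)
  ends <- run_etg_survey(g, tr)
  expect_identical(dim(ends), c(3L, 2L))
  for (i in 1:3) {
    one <- attr(simulate_etg(g[i, ], const_trace(1.0, 60)), "readout")
    expect_equal(ends[i, "b"], one, tolerance = 1e-12)
  }
  # permuting cells permutes columns only
  tr_rev <- dplyr::bind_rows(tr[tr$cell_id == "b", ], tr[tr$cell_id == "a", ])
  ends2 <- run_etg_survey(g, tr_rev)
  expect_equal(ends2[, c("a", "b")], ends[, c("a", "b")])
})

test_that("regulation sign distinguishes induction from depletion", {
  pos <- sim_etg_params(baseline_fraction = 0, K_D = Inf)
  neg <- sim_etg_params(baseline_fraction = 1, k_dpp = 0.2, k_dp = 0.001,
                        k_deph = 0.001, k_pp = 0.2, K_D = Inf)
  both <- dplyr::bind_rows(pos, neg)
  class(both) <- class(pos)
  sgn <- regulation_sign(both)
  expect_identical(sgn$sign, c("positive", "negative"))
  expect_false(any(sgn$degenerate))
})

test_that("predictivity screening matches a direct OLS oracle", {
  set.seed(41)
  ds <- small_dataset()
  f <- erk_features(ds$traces)
  # endpoint equal to the mean feature -> R^2 = 1
  ends <- rbind(exact = f$mean, noise = rnorm(nrow(f)))
  colnames(ends) <- f$cell_id
  scr <- screen_predictivity(ends, f)
  r2 <- scr$r2
  expect_equal(r2$r2[r2$gene_id == "exact" & r2$feature == "mean"], 1,
               tolerance = 1e-9)
  expect_lt(r2$r2[r2$gene_id == "noise" & r2$feature == "mean"], 0.05)
  # direct 1 - SSE/SST check for one pair
  x <- ends["noise", ]; y <- f$max
  beta <- ols_oracle(matrix(x), y)
  sse <- sum((y - beta[1] - beta[2] * x)^2)
  sst <- sum((y - mean(y))^2)
  expect_equal(r2$r2[r2$gene_id == "noise" & r2$feature == "max"],
               1 - sse / sst, tolerance = 1e-10)
})

test_that("timepoint profiles separate fast trackers from integrators", {
  ds <- small_dataset()
  keep <- ds$cells$cell_id[ds$cells$condition %in%
                             c("egf_meki12h", "egf_recent", "control")]
  tr <- ds$traces[ds$traces$cell_id %in% keep, ]
  fast <- sim_etg_params(0.05, k_dm = 0.1, k_dp = 0.1, k_dpp = 0.1,
                         gene_id = "fast")
  slow <- sim_etg_params(0.05, k_dm = 0.002, k_dp = 0.002, k_dpp = 0.002,
                         gene_id = "slow")
  both <- dplyr::bind_rows(fast, slow); class(both) <- class(fast)
  ends <- run_etg_survey(both, tr)
  prof <- survey_timepoint_profile(ends, tr)
  pf <- prof[prof$gene_id == "fast", ]
  ps <- prof[prof$gene_id == "slow", ]
  tmax <- max(pf$t_min)
  # the fast gene's correlation peaks late
  expect_gt(pf$t_min[which.max(abs(pf$r))], tmax - 240)
  # the slow integrator's profile is broad: more timepoints near its max
  breadth <- function(p) mean(abs(p$r) > 0.8 * max(abs(p$r), na.rm = TRUE),
                              na.rm = TRUE)
  expect_gt(breadth(ps), breadth(pf))
  # constant endpoint -> all correlations missing
  ends2 <- rbind(const = rep(1, ncol(ends)))
  colnames(ends2) <- colnames(ends)
  prof2 <- survey_timepoint_profile(ends2, tr)
  expect_true(all(is.na(prof2$r)))
})
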