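test_that("QC drops short, implausible, and non-finite traces", {
  mk <- function(id, n, act) tibble::tibble(cell_id = id,
                                            t_min = seq(0, by = 6,
                                                        length.out = n),
                                            activity = act)
  traces <- dplyr::bind_rows(
    mk("short", 140, rep(0.2, 140)),          # 13.9 h -> dropped
    mk("clean", 190, rep(0.2, 190)),
    mk("nonfin", 190, c(rep(0.2, 100), NA, rep(0.2, 89))),
    mk("neg", 190, c(rep(0.2, 100), -0.5, rep(0.2, 89))))
  kept <- unique(qc_traces(traces)$cell_id)
  expect_identical(kept, "clean")
  expect_error(qc_traces(traces[0, ]), "empty")
})

test_that("peak detection handles canonical shapes", {
  t <- seq(0, by = 6, length.out = 40)
  expect_identical(nrow(find_pulses(t, seq_along(t))), 0L)  # monotone

  tr <- two_pulse_trace()
  pk <- find_pulses(tr$t_min, tr$activity, min_prominence = 0.5)
  expect_identical(nrow(pk), 2L)
  expect_equal(diff(pk$t_peak), 400, tolerance = 6)

  # triangular pulse: width equals the brute-force crossing scan
  a <- c(rep(0, 10), seq(0, 1, length.out = 6), seq(0.8, 0, length.out = 5),
         rep(0, 10))
  tt <- seq(0, by = 6, length.out = length(a))
  pk2 <- find_pulses(tt, a)
  expect_identical(nrow(pk2), 1L)
  expect_equal(pk2$width_min,
               width_oracle(tt, a, pk2$peak_index, pk2$prominence))
  expect_error(find_pulses(c(0, 1, 3, 10), c(0, 1, 0, 0)), "uniform")
})

test_that("peak detection matches the brute-force prominence oracle", {
  set.seed(21)
  for (rep in 1:300) {
    n <- sample(10:200, 1)
    a <- as.numeric(cumsum(rnorm(n)))
    t <- seq(0, by = 6, length.out = n)
    thr <- runif(1, 0, 2)
    got <- find_pulses(t, a, thr)
    want <- peak_oracle(a)
    want <- want[want[, "prominence"] >= thr, , drop = FALSE]
    expect_identical(got$peak_index, as.integer(want[, "index"]))
    expect_equal(got$prominence, unname(want[, "prominence"]),
                 tolerance = 1e-12)
    expect_equal(got$height, unname(want[, "height"]), tolerance = 1e-12)
  }
})

test_that("feature identities and direct recomputation hold", {
  # constant trace: pulse features zero, interval = window, frequency 0
  tc <- tibble::tibble(cell_id = "c", t_min = seq(0, by = 6,
                                                  length.out = 190),
                       activity = 0.42)
  f <- erk_features(tc, min_prominence = 0.01)
  expect_equal(f$mean, 0.42)
  expect_equal(f$max, 0.42)
  expect_equal(f$sum_duration, 0)
  expect_equal(f$sum_peak_height, 0)
  expect_equal(f$avg_derivative, 0)
  expect_equal(f$avg_interpulse_interval, 189 * 6)
  expect_equal(f$frequency, 0)
  expect_true(f$interval_imputed)

  # random trace: direct loop recomputation of mean/max/derivative,
  # and the exact sum = avg * n identities
  set.seed(5)
  a <- abs(cumsum(rnorm(190, 0, 0.1))) + 0.1
  tr <- tibble::tibble(cell_id = "c", t_min = seq(0, by = 6,
                                                  length.out = 190),
                       activity = a)
  f2 <- erk_features(tr, min_prominence = 0.05)
  expect_equal(f2$mean, sum(a) / length(a), tolerance = 1e-12)
  expect_equal(f2$max, max(a), tolerance = 1e-12)
  dsum <- 0
  for (i in 2:length(a)) dsum <- dsum + abs(a[i] - a[i - 1])
  expect_equal(f2$avg_derivative, dsum / (length(a) - 1) / 6,
               tolerance = 1e-12)
  expect_equal(f2$sum_duration, f2$avg_duration * f2$n_peaks)
  expect_equal(f2$sum_peak_height, f2$avg_peak_height * f2$n_peaks)
})

test_that("frequency recovers sinusoid periods and is scale invariant", {
  t <- seq(0, by = 6, length.out = 190)
  for (period_h in c(1, 2, 4, 6)) {
    a <- 1 + 0.5 * sin(2 * pi * t / (period_h * 60))
    f <- erk_features(tibble::tibble(cell_id = "c", t_min = t, activity = a),
                      min_prominence = 0.01)
    expect_lt(abs(f$frequency - 1 / period_h) / (1 / period_h), 0.05)
    # invariance to additive constant and positive scaling
    f2 <- erk_features(tibble::tibble(cell_id = "c", t_min = t,
                                      activity = 3 * a + 7),
                       min_prominence = 0.01)
    expect_equal(f2$frequency, f$frequency, tolerance = 1e-10)
  }
})

test_that("timepoint correlation matches the textbook formula", {
  ds <- small_dataset()
  tc <- timepoint_correlation(ds$stains, ds$traces, targets = "Fra1")
  expect_true(all(tc$r >= -1 & tc$r <= 1, na.rm = TRUE))
  # direct check at one timepoint
  m <- ds$traces[ds$traces$t_min == 600, ]
  y <- log10(ds$stains$Fra1[match(m$cell_id, ds$stains$cell_id)])
  expect_equal(tc$r[tc$t_min == 600], pearson_oracle(m$activity, y),
               tolerance = 1e-10)

  # target equal to the final-timepoint activity -> r = 1 there;
  # negated first-timepoint activity -> r = -1 at t0
  tmax <- max(ds$traces$t_min)
  last <- ds$traces[ds$traces$t_min == tmax, ]
  first <- ds$traces[ds$traces$t_min == 0, ]
  panel <- tibble::tibble(
    cell_id = last$cell_id,
    final = 10^last$activity,
    neg0 = 10^(-first$activity[match(last$cell_id, first$cell_id)]))
  tc2 <- timepoint_correlation(panel, ds$traces)
  expect_equal(tc2$r[tc2$target == "final" & tc2$t_min == tmax], 1,
               tolerance = 1e-9)
  expect_equal(tc2$r[tc2$target == "neg0" & tc2$t_min == 0], -1,
               tolerance = 1e-9)

  # zero variance -> NA, not 0
  flat <- ds$traces
  flat$activity[flat$t_min == 0] <- 1
  tc3 <- timepoint_correlation(panel["cell_id"] |>
                                 dplyr::mutate(s = panel$final),
                               flat, targets = "s")
  expect_true(is.na(tc3$r[tc3$t_min == 0]))
})

test_that("5-cell hand computation matches", {
  tr <- purrr::map_dfr(1:5, function(i) {
    tibble::tibble(cell_id = paste0("c", i), t_min = c(0, 6, 12),
                   activity = c(i, 2 * i, i^2) / 10)
  })
  panel <- tibble::tibble(cell_id = paste0("c", 1:5),
                          s = c(2, 3, 10, 1, 5))
  tc <- timepoint_correlation(panel, tr, targets = "s",
                              log10_stains = FALSE)
  for (tt in c(0, 6, 12)) {
    x <- tr$activity[tr$t_min == tt]
    expect_equal(tc$r[tc$t_min == tt], pearson_oracle(x, panel$s),
                 tolerance = 1e-12)
  }
})
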