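# Independent oracles used across tests.  These re-derive quantities by the
# most direct method available (explicit scans, closed forms, normal
# equations) and stay independent of the package implementations they check.

# Ordinary least squares via the normal equations.
ols_oracle <- function(X, y) {
  X1 <- cbind(1, X)
  drop(solve(t(X1) %*% X1, t(X1) %*% y))
}

# Topographic prominence by exhaustive scan: for each interior strict local
# maximum, walk out to the nearest higher sample (or edge) on each side and
# take the minimum in between; prominence = height - max(left min, right min).
peak_oracle <- function(a) {
  n <- length(a)
  peaks <- list()
  for (i in 2:(n - 1)) {
    if (!(a[i] > a[i - 1] && a[i] > a[i + 1])) next
    j <- i - 1
    while (j >= 1 && a[j] <= a[i]) j <- j - 1
    lo_l <- min(a[max(j, 1):i])
    k <- i + 1
    while (k <= n && a[k] <= a[i]) k <- k + 1
    lo_r <- min(a[i:min(k, n)])
    peaks[[length(peaks) + 1]] <-
      c(index = i, height = a[i], prominence = a[i] - max(lo_l, lo_r))
  }
  do.call(rbind, peaks)
}

# Width at half prominence by direct crossing scan on a uniform grid.
width_oracle <- function(t, a, i, prom) {
  ref <- a[i] - prom / 2
  n <- length(a)
  tl <- t[1]
  for (m in seq(i - 1, 1)) {
    if (a[m] <= ref) {
      w <- (a[m + 1] - ref) / (a[m + 1] - a[m])
      tl <- t[m + 1] + w * (t[m] - t[m + 1])
      break
    }
  }
  tr <- t[n]
  for (m in seq(i + 1, n)) {
    if (a[m] <= ref) {
      w <- (a[m - 1] - ref) / (a[m - 1] - a[m])
      tr <- t[m - 1] + w * (t[m] - t[m - 1])
      break
    }
  }
  tr - tl
}

# Two-pass textbook Pearson correlation.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Benjamini-Hochberg step-up by explicit threshold search.
bh_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * alpha) k <- i
  rejected <- logical(m)
  if (k > 0) rejected[o[seq_len(k)]] <- TRUE
  rejected
}

# Closed-form steady state of the gene model without feedback, derived
# directly from the rate equations at equilibrium.
steady_oracle <- function(p, erk) {
  tfp <- p$k_ptf * erk * p$tf_total / (p$k_ptf * erk + p$k_dtf)
  m <- (p$k_b + p$k_m * tfp) / p$k_dm
  c_pp <- p$k_pp * erk / (p$k_dpp + p$k_deph)
  ceff <- p$k_dp + p$k_pp * erk - p$k_deph * c_pp
  pr <- p$k_p * m / ceff
  c(tfp = tfp, mrna = m, p = pr, pp = c_pp * pr)
}

# Small deterministic trace fixture: two clean unit pulses on a baseline.
two_pulse_trace <- function() {
  t <- seq(0, by = 6, length.out = 190)
  a <- 0.1 +
    exp(-(t - 300)^2 / (2 * 20^2)) +
    exp(-(t - 700)^2 / (2 * 20^2))
  tibble::tibble(cell_id = "cell", t_min = t, activity = a)
}

# Compact synthetic dataset shared by classifier/reverse tests (cached per
# session to keep the suite fast).
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_plate(default_layout(n_cells = 30, replicates = 3),
                               seed = 101)
    }
    cache
  }
})
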