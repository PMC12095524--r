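#' Variance-corrected two-sample t-test
#'
#' Two-sided test for a difference of group means when cells are nested in
#' experimental replicates, under the linear error model in which a cell's
#' deviation is the sum of a cell-level and an experiment-level error. Per
#' group, the pure experiment-level variance component is estimated
#' ANOVA-style as `var(replicate means) - mean(within-replicate variance) /
#' n_cells` (truncated at zero, since the variance of the replicate means
#' already contains the cell-level contribution), and the variance of the
#' group mean as `(between + within / n_cells) / n_replicates` with
#' `n_replicates - 1` degrees of freedom per group; the two groups are
#' combined Welch-style with Satterthwaite degrees of freedom.
#' The `"welch_inflated"` variant instead inflates the classical Welch
#' cell-level variance by the between-replicate variance.
#'
#' @param x,y Numeric measurement vectors for the two groups.
#' @param rep_x,rep_y Replicate identifiers aligned with `x` and `y`
#'   (>= 2 distinct values per group).
#' @param method Variance composition rule (see above).
#' @return Tibble: `t`, `df`, `p`, group means and variance components.
#' @export
vc_t_test <- function(x, rep_x, y, rep_y,
                      method = c("two_level", "welch_inflated")) {
  method <- match.arg(method)
  comp <- function(v, rep) {
    abort_if(length(unique(rep)) < 2,
             "need >= 2 replicates per group (between-replicate variance undefined)")
    means <- tapply(v, rep, mean)
    vars <- tapply(v, rep, var)
    ns <- tapply(v, rep, length)
    R <- length(means)
    within <- mean(vars, na.rm = TRUE)
    n_bar <- mean(ns)
    list(mean = mean(means),
         between = max(var(means) - within / n_bar, 0),
         within = within, n_bar = n_bar, R = R, n = length(v))
  }
  a <- comp(x, rep_x); b <- comp(y, rep_y)
  if (method == "two_level") {
    va <- (a$between + a$within / a$n_bar) / a$R
    vb <- (b$between + b$within / b$n_bar) / b$R
    dfa <- a$R - 1; dfb <- b$R - 1
  } else {
    va <- a$within / a$n + a$between
    vb <- b$within / b$n + b$between
    dfa <- a$n - 1; dfb <- b$n - 1
  }
  se2 <- va + vb
  t_stat <- if (se2 == 0) 0 else (a$mean - b$mean) / sqrt(se2)
  df <- if (se2 == 0) dfa + dfb else se2^2 / (va^2 / dfa + vb^2 / dfb)
  p <- if (se2 == 0) 1 else 2 * pt(-abs(t_stat), df)
  tibble::tibble(t = t_stat, df = df, p = p,
                 mean_x = a$mean, mean_y = b$mean,
                 between_x = a$between, within_x = a$within,
                 between_y = b$between, within_y = b$within)
}

#' Benjamini-Hochberg false discovery control
#'
#' Standard step-up procedure; adjusted p-values via [stats::p.adjust()] with
#' the rejection mask at level `alpha`.
#'
#' @param p P-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return Tibble: `p`, `p_adj`, `rejected`.
#' @export
bh_fdr <- function(p, alpha = 0.05) {
  abort_if(length(p) == 0, "empty p-value vector")
  abort_if(any(p < 0 | p > 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adj = adj, rejected = !is.na(adj) & adj <= alpha)
}

# Exact optimal leaf ordering (dynamic programming over subtree end-leaf
# pairs) for a merge tree; O(n^3)-ish, used up to `exact_max` leaves.
olo_exact <- function(merge, d) {
  n <- nrow(d)
  # node -> list(leaves, M = matrix cost keyed by (start leaf, end leaf),
  #              choice bookkeeping for reconstruction)
  nodes <- vector("list", nrow(merge))
  leaf <- function(i) list(leaves = i, M = matrix(0, 1, 1,
                                                  dimnames = list(i, i)))
  get_node <- function(j) if (j < 0) leaf(-j) else nodes[[j]]
  for (v in seq_len(nrow(merge))) {
    L <- get_node(merge[v, 1]); R <- get_node(merge[v, 2])
    ll <- L$leaves; rl <- R$leaves
    M <- matrix(Inf, length(ll) + length(rl), length(ll) + length(rl),
                dimnames = list(c(ll, rl), c(ll, rl)))
    pick <- array(NA_integer_, dim = dim(M))
    # order starts in L, ends in R (and the mirrored case)
    for (ui in seq_along(ll)) for (wi in seq_along(rl)) {
      best <- Inf; arg <- c(NA, NA)
      for (pi in seq_along(ll)) for (qi in seq_along(rl)) {
        cost <- L$M[ui, pi] + d[ll[pi], rl[qi]] + R$M[qi, wi]
        if (cost < best) { best <- cost; arg <- c(pi, qi) }
      }
      M[ui, length(ll) + wi] <- best
      M[length(ll) + wi, ui] <- best  # reversal symmetry
    }
    # orderings fully inside one child are not allowed (children stay
    # contiguous blocks), so start/end pairs within a child remain Inf
    nodes[[v]] <- list(leaves = c(ll, rl), M = M, L = L, R = R)
  }
  root <- nodes[[nrow(merge)]]
  # reconstruct by re-solving the argmin at each node (cheap relative to DP)
  reconstruct <- function(node, u, w) {
    if (length(node$leaves) == 1) return(node$leaves)
    ll <- node$L$leaves; rl <- node$R$leaves
    flip <- !(u %in% ll)
    if (flip) { tmp <- u; u <- w; w <- tmp }
    best <- Inf; arg <- c(NA, NA)
    ui <- match(u, ll); wi <- match(w, rl)
    for (pi in seq_along(ll)) for (qi in seq_along(rl)) {
      cost <- node$L$M[ui, pi] + d[ll[pi], rl[qi]] + node$R$M[qi, wi]
      if (cost < best) { best <- cost; arg <- c(pi, qi) }
    }
    out <- c(reconstruct(node$L, u, ll[arg[1]]),
             reconstruct(node$R, rl[arg[2]], w))
    if (flip) rev(out) else out
  }
  ends <- which(root$M == min(root$M), arr.ind = TRUE)[1, ]
  reconstruct(root, root$leaves[ends[1]], root$leaves[ends[2]])
}

# Greedy branch-flip ordering: at each merge choose the child orientations
# minimizing the distance across the junction.
olo_greedy <- function(merge, d) {
  orient <- function(j) {
    if (j < 0) return(-j)
    L <- orient(merge[j, 1]); R <- orient(merge[j, 2])
    combos <- list(c(L, R), c(rev(L), R), c(L, rev(R)), c(rev(L), rev(R)))
    cost <- vapply(combos, function(o) {
      d[o[length(L)], o[length(L) + 1]]
    }, numeric(1))
    combos[[which.min(cost)]]
  }
  orient(nrow(merge))
}

#' Order cells spatially by hierarchical clustering with optimal leaf order
#'
#' Average-linkage hierarchical clustering of the pairwise Euclidean distance
#' matrix of cell coordinates, with the leaf order chosen to minimize the
#' summed distance between adjacent leaves by flipping tree branches (never
#' splitting clusters). Up to `exact_max` cells the exact dynamic-programming
#' optimum is computed; beyond that a greedy branch-flip pass is used.
#'
#' @param cells Table with `cell_id`, `x_um`, `y_um`.
#' @param exact_max Size limit for the exact ordering (default 200).
#' @return List of class `spatial_ordering`: `cell_id` (ordered), `method`,
#'   `adjacent_mean` (mean distance between ordered neighbors), `hclust`.
#' @export
spatial_order <- function(cells, exact_max = 200) {
  abort_if(nrow(cells) < 2, "need at least 2 cells")
  abort_if(any(!is.finite(cells$x_um) | !is.finite(cells$y_um)),
           "coordinates must be finite")
  dm <- as.matrix(dist(cells[, c("x_um", "y_um")]))
  hc <- hclust(as.dist(dm), method = "average")
  ord <- if (nrow(cells) <= exact_max) {
    olo_exact(hc$merge, dm)
  } else {
    olo_greedy(hc$merge, dm)
  }
  adj <- mean(dm[cbind(ord[-length(ord)], ord[-1])])
  structure(list(cell_id = cells$cell_id[ord], order = ord,
                 method = if (nrow(cells) <= exact_max) "exact" else "greedy",
                 adjacent_mean = adj, hclust = hc),
            class = "spatial_ordering")
}

#' @export
print.spatial_ordering <- function(x, ...) {
  cat("Spatial ordering of", length(x$order), "cells (", x$method,
      "); mean adjacent distance =", signif(x$adjacent_mean, 4), "\n")
  invisible(x)
}
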