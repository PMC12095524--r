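# Internal helpers.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All package randomness funnels through this so no global state leaks.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

abort_if <- function(cond, msg) {
  if (cond) rlang::abort(msg)
}

# Column-checked extraction of a wide trace matrix (cells x timepoints) from
# a long trace table.  Times must form a shared uniform grid.
trace_matrix <- function(traces) {
  abort_if(!all(c("cell_id", "t_min", "activity") %in% names(traces)),
           "`traces` must have columns cell_id, t_min, activity")
  wide <- tidyr::pivot_wider(traces[, c("cell_id", "t_min", "activity")],
                             names_from = "t_min", values_from = "activity")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$cell_id
  t_min <- as.numeric(colnames(m))
  ord <- order(t_min)
  m <- m[, ord, drop = FALSE]
  attr(m, "t_min") <- t_min[ord]
  m
}

check_uniform_sampling <- function(t_min) {
  d <- diff(sort(unique(t_min)))
  abort_if(length(d) > 0 && max(abs(d - d[1])) > 1e-8 * max(d[1], 1),
           "trace sampling must be uniform")
  if (length(d) == 0) NA_real_ else d[1]
}

# Out-of-sample coefficient of determination.
r_squared <- function(obs, pred) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((obs - pred)^2) / sst
}

# Least squares via SVD pseudoinverse: tolerant of exact collinearity.
pinv_lsfit <- function(X, y, intercept = TRUE) {
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  sv <- svd(X)
  pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  beta <- drop(beta)
  names(beta) <- colnames(X)
  beta
}

stain_targets <- function(stains) {
  setdiff(names(stains), c("cell_id", "well", "condition", "replicate",
                           "cell_line", "x_um", "y_um"))
}
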