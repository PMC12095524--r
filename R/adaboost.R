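# AdaBoost.M2 multiclass boosting over shallow regression trees.
#
# The M2 variant maintains a weight for every (example, wrong label) pair and
# trains each weak learner on the induced example weights; the weak learner's
# class-probability outputs define the pseudo-loss.  Weak learners are
# depth-limited rpart trees.

fit_weak_tree <- function(X, y, w, maxdepth) {
  d <- cbind(data.frame(.y = y), X)
  rpart::rpart(.y ~ ., data = d, weights = w / mean(w), method = "class",
               control = rpart::rpart.control(
                 maxdepth = maxdepth, cp = 0, minsplit = 4, minbucket = 2,
                 xval = 0, maxsurrogate = 0, maxcompete = 0))
}

adaboost_m2 <- function(X, y, n_rounds = 500, maxdepth = 2, seed = 1) {
  y <- factor(y)
  classes <- levels(y)
  K <- length(classes)
  n <- length(y)
  abort_if(K < 2, "need at least 2 classes")
  yi <- as.integer(y)

  # weight over (example, wrong label) pairs
  W <- matrix(1 / (n * (K - 1)), n, K)
  W[cbind(seq_len(n), yi)] <- 0

  trees <- vector("list", n_rounds)
  alphas <- numeric(n_rounds)
  used <- 0L
  with_seed(seed, {
    for (t in seq_len(n_rounds)) {
      D <- rowSums(W)
      tree <- fit_weak_tree(X, y, D, maxdepth)
      H <- predict(tree, X, type = "prob")
      H <- H[, classes, drop = FALSE]
      h_true <- H[cbind(seq_len(n), yi)]
      # pseudo-loss over the weighted wrong labels
      eps <- 0.5 * sum(W * (1 - h_true + H))
      eps <- min(max(eps, 1e-10), 1 - 1e-10)
      if (eps >= 0.5) break
      beta <- eps / (1 - eps)
      used <- used + 1L
      trees[[used]] <- tree
      alphas[used] <- log(1 / beta)
      expo <- 0.5 * (1 + h_true - H)
      W <- W * beta^expo
      W[cbind(seq_len(n), yi)] <- 0
      W <- W / sum(W)
    }
  })
  abort_if(used == 0L, "boosting failed: first weak learner no better than chance")
  structure(list(trees = trees[seq_len(used)], alphas = alphas[seq_len(used)],
                 classes = classes, n_rounds = n_rounds, maxdepth = maxdepth),
            class = "adaboost_m2")
}

#' @exportS3Method stats::predict
predict.adaboost_m2 <- function(object, newdata, type = c("class", "score"),
                                ...) {
  type <- match.arg(type)
  score <- matrix(0, nrow(newdata), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (i in seq_along(object$trees)) {
    H <- predict(object$trees[[i]], newdata, type = "prob")
    score <- score + object$alphas[i] * H[, object$classes, drop = FALSE]
  }
  if (type == "score") return(score)
  factor(object$classes[max.col(score, ties.method = "first")],
         levels = object$classes)
}

# Summed split improvement per predictor across all weak learners.
# Only primary splits are credited (competitor/surrogate rows are excluded
# at fit time via maxcompete = maxsurrogate = 0).
adaboost_importance <- function(object, predictors) {
  imp <- setNames(numeric(length(predictors)), predictors)
  for (tree in object$trees) {
    s <- tree$splits
    if (is.null(s) || nrow(s) == 0) next
    for (r in seq_len(nrow(s))) {
      v <- rownames(s)[r]
      if (v %in% predictors) imp[v] <- imp[v] + s[r, "improve"]
    }
  }
  imp
}
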