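## The pairwise min-product kernel and the classifier-adapter contract.
## Any learner satisfying the contract (fit on training rows only, scores
## in [0,1] with higher = more likely positive, deterministic per seed) can
## be audited; a decision forest and a pair-kernel SVM are bundled.

#' Pairwise min-product kernel
#'
#' Similarity between two protein pairs (A, B) and (C, D):
#' `K = exp(-gamma * min(||A-C||^2 * ||B-D||^2, ||A-D||^2 * ||B-C||^2))`.
#' The min over the two orientation matchings makes the kernel invariant
#' to the order of the proteins within either pair, encoding the
#' non-directionality of interactions.
#'
#' @param A,B Feature vectors of the first pair's proteins.
#' @param C,D Feature vectors of the second pair's proteins.
#' @param gamma Positive kernel width.
#' @return Kernel value in (0, 1].
#' @export
pair_kernel <- function(A, B, C, D, gamma = 1) {
  stopifnot(gamma > 0)
  lens <- c(length(A), length(B), length(C), length(D))
  if (length(unique(lens)) != 1) {
    abort("all four vectors must share one dimension")
  }
  m1 <- sum((A - C)^2) * sum((B - D)^2)
  m2 <- sum((A - D)^2) * sum((B - C)^2)
  exp(-gamma * min(m1, m2))
}

sqdist_cross <- function(U, V) {
  ## squared euclidean distances between rows of U and rows of V
  d2 <- outer(rowSums(U^2), rowSums(V^2), "+") - 2 * tcrossprod(U, V)
  pmax(d2, 0)
}

## The min over the two orientation matchings of the product of squared
## distances (the kernel's argument), for all row pairs of X1 x X2.
min_products <- function(X1, X2 = X1) {
  stopifnot(ncol(X1) %% 2 == 0, ncol(X1) == ncol(X2))
  d <- ncol(X1) / 2
  A <- X1[, seq_len(d), drop = FALSE]
  B <- X1[, d + seq_len(d), drop = FALSE]
  C <- X2[, seq_len(d), drop = FALSE]
  D <- X2[, d + seq_len(d), drop = FALSE]
  m1 <- sqdist_cross(A, C) * sqdist_cross(B, D)
  m2 <- sqdist_cross(A, D) * sqdist_cross(B, C)
  pmin(m1, m2)
}

#' Gram matrix of the pairwise min-product kernel
#'
#' @param X1,X2 Matrices of concatenated pair rows `[v_a, v_b]` (even
#'   column count); `X2` defaults to `X1`.
#' @param gamma Positive kernel width.
#' @return `nrow(X1) x nrow(X2)` kernel matrix.
#' @export
pair_kernel_matrix <- function(X1, X2 = X1, gamma = 1) {
  stopifnot(gamma > 0)
  exp(-gamma * min_products(X1, X2))
}

new_adapter <- function(name, hyper, symmetric, class) {
  structure(
    list(name = name, hyper = hyper, symmetric = symmetric, fit = NULL),
    class = c(class, "pair_adapter")
  )
}

#' @export
print.pair_adapter <- function(x, ...) {
  cat("<pair_adapter>", x$name,
      if (is.null(x$fit)) "(untrained)" else "(trained)", "\n")
  hp <- paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", ")
  if (nzchar(hp)) cat("  ", hp, "\n")
  invisible(x)
}

#' Decision-forest adapter
#'
#' A probability random forest over concatenated pair-feature rows.
#'
#' @param num_trees Number of trees.
#' @param mtry Features tried per split; default `sqrt(p)`.
#' @param symmetric Train on (and score with) both pair orientations.
#' @return An untrained `pair_adapter`.
#' @export
adapter_forest <- function(num_trees = 300L, mtry = NULL, symmetric = FALSE) {
  new_adapter("forest", list(num_trees = num_trees, mtry = mtry),
              symmetric, "adapter_forest")
}

#' Pair-kernel support-vector-machine adapter
#'
#' An SVM over the precomputed Gram matrix of [pair_kernel_matrix()];
#' decision values are mapped to (0, 1) by the logistic function (AUC is
#' rank-based, so any monotone map is safe).
#'
#' @param gamma Kernel width of the pairwise min-product kernel, or
#'   `"auto"` to set it to the reciprocal of the median nonzero
#'   min-product over the training Gram (a standard median heuristic that
#'   adapts the width to the feature scale).
#' @param cost Soft-margin cost.
#' @param symmetric Unused for this adapter: the kernel is already
#'   invariant to within-pair orientation.
#' @return An untrained `pair_adapter`.
#' @export
adapter_kernel_svm <- function(gamma = "auto", cost = 1, symmetric = FALSE) {
  rlang::check_installed("kernlab")
  new_adapter("kernel_svm", list(gamma = gamma, cost = cost),
              symmetric = FALSE, "adapter_kernel_svm")
}

#' Fit an adapter on pair-feature rows
#'
#' @param adapter An untrained (or previously trained, to be refit)
#'   `pair_adapter`.
#' @param x Numeric matrix of pair-feature rows.
#' @param labels Integer 0/1 labels aligned with `x` rows.
#' @param seed Integer seed; training is deterministic given
#'   (hyperparameters, data, seed).
#' @return The trained adapter.
#' @export
fit_adapter <- function(adapter, x, labels, seed = 1L) {
  stopifnot(nrow(x) == length(labels))
  if (length(unique(labels)) < 2) {
    abort("training data must contain both classes")
  }
  UseMethod("fit_adapter")
}

#' @export
fit_adapter.adapter_forest <- function(adapter, x, labels, seed = 1L) {
  colnames(x) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  adapter$fit <- ranger::ranger(
    x = x, y = factor(labels, levels = c(0L, 1L)),
    num.trees = adapter$hyper$num_trees,
    mtry = adapter$hyper$mtry,
    probability = TRUE, seed = seed, num.threads = 1
  )
  adapter
}

#' @export
fit_adapter.adapter_kernel_svm <- function(adapter, x, labels, seed = 1L) {
  m <- min_products(x)
  gamma <- adapter$hyper$gamma
  if (identical(gamma, "auto")) {
    nz <- m[m > 0]
    if (length(nz) == 0) {
      abort("cannot set gamma automatically: all pairwise min-products are zero (degenerate features); supply a numeric gamma")
    }
    gamma <- 1 / stats::median(nz)
  }
  fit <- withr::with_seed(seed, kernlab::ksvm(
    kernlab::as.kernelMatrix(exp(-gamma * m)),
    factor(labels, levels = c(0L, 1L)),
    C = adapter$hyper$cost, type = "C-svc"
  ))
  adapter$fit <- list(svm = fit, x_train = x, gamma = gamma)
  adapter
}

#' Score pair-feature rows with a trained adapter
#'
#' @param adapter A trained `pair_adapter`.
#' @param x Numeric matrix with the same columns as the training rows.
#' @return Scores in \[0, 1\], higher = more likely positive.
#' @export
score_rows <- function(adapter, x) {
  if (is.null(adapter$fit)) abort("adapter is untrained; call fit_adapter()")
  UseMethod("score_rows")
}

#' @export
score_rows.adapter_forest <- function(adapter, x) {
  colnames(x) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  predict(adapter$fit, data = x, num.threads = 1)$predictions[, "1"]
}

#' @export
score_rows.adapter_kernel_svm <- function(adapter, x) {
  K <- pair_kernel_matrix(x, adapter$fit$x_train,
                          gamma = adapter$fit$gamma)
  sv <- kernlab::SVindex(adapter$fit$svm)
  dec <- kernlab::predict(adapter$fit$svm,
                          kernlab::as.kernelMatrix(K[, sv, drop = FALSE]),
                          type = "decision")
  plogis(as.numeric(dec))
}

#' Fit an adapter from a feature map and a pair table
#'
#' Builds the pair-feature rows (both orientations when the adapter is
#' symmetric) and fits.
#'
#' @param adapter An untrained `pair_adapter`.
#' @param fm A `feature_map`.
#' @param pairs Training pair table with labels.
#' @param seed Integer seed.
#' @return The trained adapter.
#' @export
fit_pair_model <- function(adapter, fm, pairs, seed = 1L) {
  x <- pair_features(fm, pairs, symmetric = adapter$symmetric)
  labels <- pairs$label[attr(x, "pair_index")]
  fit_adapter(adapter, x, labels, seed = seed)
}

#' Score a pair table with a trained adapter
#'
#' Symmetric adapters score both orientations of every pair and average.
#'
#' @param adapter A trained `pair_adapter`.
#' @param fm A `feature_map`.
#' @param pairs Pair table to score.
#' @return One score in \[0, 1\] per pair.
#' @export
predict_pairs <- function(adapter, fm, pairs) {
  x <- pair_features(fm, pairs, symmetric = adapter$symmetric)
  s <- score_rows(adapter, x)
  idx <- attr(x, "pair_index")
  as.numeric(rowsum(s, idx)) / tabulate(idx)  # orientation-averaged
}

#' Hyperparameter selection on a validation set
#'
#' Fits one adapter per grid entry on the round's training pairs, scores
#' the validation pairs, and returns the entry with the highest validation
#' AUC (ties broken by grid order) together with the full selection table.
#'
#' @param factory Function taking one named list of hyperparameters and
#'   returning an untrained `pair_adapter`.
#' @param grid List of named hyperparameter lists (non-empty).
#' @param fm A `feature_map`.
#' @param train,validation Pair tables.
#' @param seed Integer seed.
#' @return List with elements `adapter` (the winning trained adapter),
#'   `best` (its hyperparameters) and `table` (tibble of setting and
#'   validation AUC).
#' @export
grid_select <- function(factory, grid, fm, train, validation, seed = 1L) {
  if (length(grid) == 0) abort("hyperparameter grid must be non-empty")
  fits <- lapply(grid, function(params) {
    fit_pair_model(do.call(factory, params), fm, train, seed = seed)
  })
  val_auc <- vapply(fits, function(ad) {
    auc_from_scored(predict_pairs(ad, fm, validation), validation$label)
  }, numeric(1))
  best <- which.max(val_auc)  # ties: first in grid order
  table <- tibble(
    setting = vapply(grid, function(g) {
      paste(names(g), unlist(g), sep = "=", collapse = ",")
    }, character(1)),
    validation_auc = val_auc
  )
  list(adapter = fits[[best]], best = grid[[best]], table = table)
}
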