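#' Gaussian radial basis kernel between two point sets
#'
#' `K[a, i] = exp(-||x_a - mu_i||^2 / (2 sigma^2))`, computed block-wise in
#' `A` rows so the full n x n design matrix never has to be materialised
#' when only its cross-products are needed.
#'
#' @param A Query matrix (rows = points).
#' @param B Centre matrix (rows = centres), same column count as `A`.
#' @param bandwidth Kernel bandwidth sigma > 0.
#' @return `nrow(A)` x `nrow(B)` kernel matrix with entries in (0, 1].
#' @export
rbf_kernel <- function(A, B, bandwidth = 5) {
  if (ncol(A) != ncol(B))
    .stop_fmt("feature width mismatch: %d vs %d", ncol(A), ncol(B))
  if (bandwidth <= 0) .stop_fmt("bandwidth must be > 0")
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0                       # numerical noise on the diagonal
  exp(-d2 / (2 * bandwidth^2))
}

#' Train a radial basis function network classifier
#'
#' Every training vector becomes a kernel centre (no subsampling); two
#' output nodes carry one-hot 0/1 targets for the non-binding and binding
#' class, and the output weights solve the ridge-regularised least-squares
#' problem `(Phi' Phi + lambda I) W = Phi' T` over the Gaussian design
#' matrix `Phi[a, i] = exp(-||x_a - mu_i||^2 / (2 sigma^2))`.
#'
#' With `ridge = 0` the square design matrix (centres = training points)
#' is solved directly, `Phi W = T`, which for distinct points interpolates
#' the targets exactly. The design matrix is n x n, so training cost and
#' memory are O(n^2); the normal-equation accumulation streams over row
#' blocks (`block` rows at a time) to bound the peak allocation.
#'
#' @param X Numeric feature matrix (rows = training windows).
#' @param y Binary labels (logical or 0/1), `TRUE`/1 = binding.
#' @param bandwidth Kernel bandwidth sigma (default 5).
#' @param ridge Regularisation lambda >= 0 (default 1e-8).
#' @param block Row-block size for streaming the design matrix.
#' @return An object of class `rbfn_model` with elements `centers`,
#'   `bandwidth`, `ridge`, `weights` (centres x 2) and `class_labels`
#'   (`c("non-binding", "binding")`).
#' @export
rbfn_train <- function(X, y, bandwidth = 5, ridge = 1e-8, block = 2048L) {
  X <- as.matrix(X)
  y <- as.logical(y)
  if (nrow(X) < 2L) .stop_fmt("need at least 2 training samples")
  if (length(y) != nrow(X)) .stop_fmt("X and y sizes disagree")
  if (length(unique(y)) < 2L) .stop_fmt("both classes must be present")
  if (ridge < 0) .stop_fmt("ridge must be >= 0")
  targets <- cbind(`non-binding` = as.numeric(!y), binding = as.numeric(y))
  n <- nrow(X)
  if (ridge == 0) {
    Phi <- rbf_kernel(X, X, bandwidth)
    W <- tryCatch(solve(Phi, targets), error = function(e)
      .stop_fmt("singular design matrix at ridge = 0 (duplicate training rows?); use ridge > 0"))
  } else {
    G <- matrix(0, n, n)                 # Phi' Phi accumulated over blocks
    R <- matrix(0, n, 2L)
    for (s in seq(1L, n, by = block)) {
      e <- min(s + block - 1L, n)
      Phi_b <- rbf_kernel(X[s:e, , drop = FALSE], X, bandwidth)
      G <- G + crossprod(Phi_b)
      R <- R + crossprod(Phi_b, targets[s:e, , drop = FALSE])
    }
    W <- solve(G + diag(ridge, n), R)
  }
  structure(list(centers = X, bandwidth = bandwidth, ridge = ridge,
                 weights = W, class_labels = c("non-binding", "binding")),
            class = "rbfn_model")
}

#' @export
print.rbfn_model <- function(x, ...) {
  cat(sprintf("<rbfn_model> %d centres, %d features, sigma = %g, lambda = %g\n",
              nrow(x$centers), ncol(x$centers), x$bandwidth, x$ridge))
  invisible(x)
}

#' Output-node decision values of a trained RBFN
#'
#' `g_j(x) = sum_i w_ji phi(||x - mu_i||; sigma)`, one column per output
#' node (non-binding, binding).
#'
#' @param model An `rbfn_model`.
#' @param X Feature matrix with the training feature width.
#' @param block Row-block size for streaming.
#' @return `nrow(X)` x 2 matrix of decision values.
#' @export
rbfn_decision_values <- function(model, X, block = 2048L) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$centers))
    .stop_fmt("feature width %d does not match the %d model features",
              ncol(X), ncol(model$centers))
  out <- matrix(0, nrow(X), 2L,
                dimnames = list(NULL, model$class_labels))
  for (s in seq(1L, nrow(X), by = block)) {
    e <- min(s + block - 1L, nrow(X))
    out[s:e, ] <- rbf_kernel(X[s:e, , drop = FALSE], model$centers,
                             model$bandwidth) %*% model$weights
  }
  out
}

#' Predict binding labels with a trained RBFN
#'
#' The predicted class is the output node with the larger decision value;
#' an exact tie resolves to non-binding. The returned score,
#' `g_binding - g_nonbinding`, orders windows for ROC analysis.
#'
#' @inheritParams rbfn_decision_values
#' @param threshold Score threshold for calling a site binding
#'   (default 0 = argmax rule).
#' @return Data frame with columns `label` (logical, `TRUE` = binding) and
#'   `score`.
#' @export
rbfn_predict <- function(model, X, threshold = 0) {
  g <- rbfn_decision_values(model, X)
  score <- g[, "binding"] - g[, "non-binding"]
  data.frame(label = score > threshold, score = score)
}
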