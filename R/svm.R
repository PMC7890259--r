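#' Fit a two-class C-SVM on a feature matrix
#'
#' A thin interface over the package's deterministic SMO solver (the same
#' quadratic-programming core used inside [searchlight_map()]).  Labels are
#' coded internally as -1 (group `A`) / +1 (group `B`); the decision function
#' is `f(x) = sum_i alpha_i y_i K(x_i, x) + b`, and a point is assigned to
#' group `B` when `f(x) >= 0`.  A single-class training set degenerates to a
#' majority-rule predictor.
#'
#' @param x Numeric feature matrix (rows = observations).
#' @param labels Character/factor vector of `"A"`/`"B"` labels.
#' @param C Regularization constant (> 0).
#' @param kernel `"linear"` or `"rbf"`.
#' @param gamma RBF kernel width (required for `kernel = "rbf"`).
#' @return Object of class `svm_fit` with a [predict()][predict.svm_fit]
#'   method.
#' @export
svm_fit <- function(x, labels, C = 1, kernel = c("linear", "rbf"), gamma = NULL) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- label_codes(labels)
  if (length(y) != nrow(x)) stopf("svm_fit: %d labels for %d rows", length(y), nrow(x))
  if (!is.numeric(C) || C <= 0) stopf("svm_fit: 'C' must be > 0")
  if (kernel == "rbf" && (is.null(gamma) || gamma <= 0))
    stopf("svm_fit: 'gamma' must be > 0 for the rbf kernel")
  K <- kernel_matrix(x, x, kernel, gamma)
  sol <- .cpp_svm_train(K, y, C)
  structure(list(x = x, y = y, alpha = sol$alpha, b = sol$b,
                 majority = sol$majority, majority_label = sol$majority_label,
                 kernel = kernel, gamma = gamma, C = C),
            class = "svm_fit")
}

#' @param object An `svm_fit` object.
#' @param newdata Feature matrix of points to classify.
#' @param decision Return raw decision values instead of labels.
#' @param ... Unused.
#' @rdname svm_fit
#' @export
predict.svm_fit <- function(object, newdata, decision = FALSE, ...) {
  newdata <- as.matrix(newdata)
  if (object$majority) {
    dec <- rep(object$majority_label * Inf, nrow(newdata))
  } else {
    K <- kernel_matrix(newdata, object$x, object$kernel, object$gamma)
    dec <- as.vector(K %*% (object$alpha * object$y)) + object$b
  }
  if (decision) return(dec)
  ifelse(dec >= 0, "B", "A")
}

label_codes <- function(labels) {
  l <- as.character(labels)
  bad <- setdiff(unique(l), c("A", "B"))
  if (length(bad)) stopf("labels must be 'A' or 'B' (found: %s)", paste(bad, collapse = ", "))
  ifelse(l == "B", 1L, -1L)
}

kernel_matrix <- function(x, y, kernel, gamma = NULL) {
  if (kernel == "linear") return(tcrossprod(x, y))
  d2 <- outer(rowSums(x^2), rowSums(y^2), `+`) - 2 * tcrossprod(x, y)
  exp(-gamma * pmax(d2, 0))
}

# Deterministic stratified fold assignment shared by the fast and reference
# searchlight engines (and the ROC module).  Returns 1-based fold ids.
stratified_fold_assignment <- function(labels, k, seed, voxel_index = 0, outer_index = 0) {
  y <- label_codes(labels)
  .cpp_inner_folds(y, as.integer(k), as.numeric(seed),
                   as.numeric(voxel_index), as.numeric(outer_index)) + 1L
}
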