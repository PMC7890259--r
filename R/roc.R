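#' Region-mean GM features from a cluster table
#'
#' One feature per cluster: the mean GM value over the cluster's voxels,
#' computed per subject.  This is the feature set of the discrimination
#' benchmark comparing detected-region sets (e.g. MVPA clusters vs VBM
#' clusters).
#'
#' @param cohort A [cohort_volumes()] object.
#' @param clusters A `cluster_table` (with its label volume attached), or a
#'   list of cluster tables whose regions are concatenated.
#' @return A `feature_matrix`: list with `x` (subjects x regions) and
#'   `labels`.
#' @export
region_mean_features <- function(cohort, clusters) {
  tabs <- if (inherits(clusters, "cluster_table")) list(clusters) else clusters
  volmat <- cohort_matrix(cohort)
  cols <- list()
  for (tb in tabs) {
    if (nrow(tb) == 0L) next
    labels <- attr(tb, "labels")
    if (is.null(labels)) stopf("region_mean_features: cluster table lacks its label volume")
    for (id in tb$id) {
      vox <- which(labels == id)
      if (length(vox) == 0L) stopf("region_mean_features: cluster %d is empty", id)
      cols[[length(cols) + 1L]] <- rowMeans(volmat[, vox, drop = FALSE])
    }
  }
  if (length(cols) == 0L) stopf("region_mean_features: no clusters given")
  x <- do.call(cbind, cols)
  colnames(x) <- sprintf("region_%02d", seq_len(ncol(x)))
  structure(list(x = x, labels = cohort$subjects$group),
            class = "feature_matrix")
}

#' Cross-validated SVM class probabilities
#'
#' Stratified k-fold cross-validation of an SVM on region-mean features: in
#' each fold the classifier is trained on the remaining folds — with `(C,
#' gamma)` chosen by a nested inner cross-validation — and the held-out
#' subjects receive out-of-fold predicted probabilities of belonging to the
#' case group (`B`).  Each subject is predicted exactly once.
#'
#' SVM decision values come from [e1071::svm()]; they are mapped to
#' probabilities by Platt sigmoid scaling fitted (by deterministic Newton
#' iteration) to cross-validated decision values of the training fold only,
#' so there is no leakage and, given `seed`, the result is exactly
#' reproducible.
#'
#' @param features A `feature_matrix` or numeric matrix.
#' @param labels `"A"`/`"B"` labels (taken from a `feature_matrix`).
#' @param folds Number of outer folds (default 5).
#' @param seed Seed for the stratified fold assignment.
#' @param kernel `"linear"` or `"radial"`.
#' @param c_grid,g_grid Hyperparameter grids for the nested selection.
#' @param inner_folds Inner folds of the nested selection (default 3).
#' @return Object of class `roc_report` with the pooled `samples` data frame
#'   (`id`, `label`, `prob`, `fold`); metrics are filled in by
#'   [roc_metrics()].
#' @export
cv_predicted_probabilities <- function(features, labels = NULL, folds = 5L,
                                       seed = 1L, kernel = c("linear", "radial"),
                                       c_grid = 2^seq(-5, 9, by = 2),
                                       g_grid = 2^seq(-9, 3, by = 2),
                                       inner_folds = 3L) {
  kernel <- match.arg(kernel)
  if (inherits(features, "feature_matrix")) {
    labels <- features$labels
    x <- features$x
  } else x <- as.matrix(features)
  labels <- as.character(labels)
  n <- nrow(x)
  counts <- table(factor(labels, levels = c("A", "B")))
  if (any(counts < folds))
    stopf("cv_predicted_probabilities: group %s has %d member(s), fewer than %d folds; use fewer folds",
          names(counts)[which.min(counts)], min(counts), folds)

  pairs <- if (kernel == "linear") data.frame(C = sort(c_grid), gamma = NA_real_)
           else expand.grid(gamma = sort(g_grid), C = sort(c_grid))[, c("C", "gamma")]
  pairs <- pairs[order(pairs$C, pairs$gamma), , drop = FALSE]

  fold_id <- stratified_fold_assignment(labels, folds, seed)
  prob <- rep(NA_real_, n)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    xt <- x[tr, , drop = FALSE]
    lt <- labels[tr]
    best <- select_svm_pair(xt, lt, pairs, kernel, inner_folds, seed, f)
    dec_test <- svm_decision_b(xt, lt, x[!tr, , drop = FALSE], kernel, best$C, best$gamma)
    # Platt calibration on inner-CV decision values of the training fold
    calib_fold <- stratified_fold_assignment(lt, inner_folds, seed,
                                             voxel_index = f, outer_index = folds + 1L)
    dec_cv <- rep(NA_real_, sum(tr))
    for (g in seq_len(inner_folds)) {
      inn <- calib_fold != g
      if (all(inn) || !any(inn)) next
      dec_cv[!inn] <- svm_decision_b(xt[inn, , drop = FALSE], lt[inn],
                                     xt[!inn, , drop = FALSE], kernel,
                                     best$C, best$gamma)
    }
    ok <- !is.na(dec_cv)
    ab <- platt_fit(dec_cv[ok], lt[ok] == "B")
    prob[!tr] <- platt_prob(dec_test, ab)
  }
  samples <- data.frame(id = if (!is.null(rownames(x))) rownames(x) else sprintf("S%03d", seq_len(n)),
                        label = labels, prob = prob, fold = fold_id,
                        stringsAsFactors = FALSE)
  structure(list(samples = samples, auc = NULL, sensitivity = NULL,
                 specificity = NULL, ppv = NULL, npv = NULL,
                 threshold = NULL, threshold_rule = NULL),
            class = "roc_report")
}

# Nested grid selection by inner-CV accuracy; ties -> smallest C then gamma.
select_svm_pair <- function(x, labels, pairs, kernel, inner_folds, seed, outer_index) {
  if (nrow(pairs) == 1L) return(pairs[1, ])
  fold <- stratified_fold_assignment(labels, inner_folds, seed,
                                     voxel_index = 0L, outer_index = outer_index)
  best <- pairs[1, ]; best_correct <- -1L
  for (p in seq_len(nrow(pairs))) {
    corr <- 0L
    for (g in seq_len(inner_folds)) {
      tr <- fold != g
      if (all(tr) || !any(tr)) next
      dec <- svm_decision_b(x[tr, , drop = FALSE], labels[tr],
                            x[!tr, , drop = FALSE], kernel, pairs$C[p], pairs$gamma[p])
      pred <- ifelse(dec >= 0, "B", "A")
      corr <- corr + sum(pred == labels[!tr])
    }
    if (corr > best_correct) { best_correct <- corr; best <- pairs[p, ] }
  }
  best
}

# Decision values oriented so that positive = class "B", via e1071; a
# single-class training set degenerates to a constant majority decision.
svm_decision_b <- function(xtr, ltr, xte, kernel, C, gamma) {
  if (length(unique(ltr)) < 2L)
    return(rep(if (ltr[1] == "B") 1e6 else -1e6, nrow(xte)))
  y <- factor(ltr, levels = c("A", "B"))
  m <- e1071::svm(xtr, y, kernel = kernel, cost = C,
                  gamma = if (is.na(gamma)) 1 / ncol(xtr) else gamma,
                  scale = FALSE)
  pr <- predict(m, xte, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  pos_class <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  as.vector(dv) * if (pos_class == "B") 1 else -1
}

# Platt sigmoid fit (regularized targets, Newton with backtracking).
# f: decision values; y: logical, TRUE = positive class.
platt_fit <- function(f, y) {
  n1 <- sum(y); n0 <- sum(!y)
  hi <- (n1 + 1) / (n1 + 2); lo <- 1 / (n0 + 2)
  t <- ifelse(y, hi, lo)
  A <- 0; B <- log((n0 + 1) / (n1 + 1))
  sigma <- 1e-12
  objective <- function(A, B) {
    fApB <- A * f + B
    sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  fval <- objective(A, B)
  for (it in 1:100) {
    fApB <- A * f + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
    d2 <- p * (1 - p)
    h11 <- sigma + sum(f * f * d2); h22 <- sigma + sum(d2); h21 <- sum(f * d2)
    d1 <- t - p
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    det <- h11 * h22 - h21^2
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= 1e-10) {
      newf <- objective(A + step * dA, B + step * dB)
      if (newf < fval + 1e-4 * step * gd) {
        A <- A + step * dA; B <- B + step * dB; fval <- newf
        break
      }
      step <- step / 2
    }
    if (step < 1e-10) break
  }
  c(A = A, B = B)
}

platt_prob <- function(f, ab) {
  fApB <- ab[1] * f + ab[2]
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

#' Area under the ROC curve by the rank method
#'
#' Mann-Whitney AUC: the probability that a random case (`B`) receives a
#' higher score than a random control (`A`), with ties counted half, computed
#' from midranks.  Equals the trapezoidal area under the empirical ROC curve.
#'
#' @param prob Numeric scores (higher = more case-like).
#' @param labels `"A"`/`"B"` labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(prob, labels) {
  y <- as.character(labels) == "B"
  np <- sum(y); nn <- sum(!y)
  if (np == 0L || nn == 0L) stopf("roc_auc: both classes must be present")
  r <- rank(prob)
  (sum(r[y]) - np * (np + 1) / 2) / (np * nn)
}

#' Complete a cross-validated ROC report
#'
#' Computes AUC (rank method) and the operating-point metrics —
#' sensitivity, specificity, positive and negative predictive value — from
#' the pooled out-of-fold probabilities.  A subject is called a case when its
#' probability is `>= threshold`.
#'
#' @param report A `roc_report` from [cv_predicted_probabilities()].
#' @param threshold_rule `"fixed"` (use `threshold`, default 0.5) or
#'   `"youden"` (maximize sensitivity + specificity - 1 over observed
#'   probabilities; data-dependent, ties broken by the smallest threshold).
#' @param threshold Operating threshold for `threshold_rule = "fixed"`.
#' @return The completed `roc_report` (fields `auc`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `threshold`).
#' @export
roc_metrics <- function(report, threshold_rule = c("fixed", "youden"),
                        threshold = 0.5) {
  threshold_rule <- match.arg(threshold_rule)
  s <- report$samples
  if (length(unique(s$label)) < 2L)
    stopf("roc_metrics: both classes must be present")
  if (anyNA(s$prob)) stopf("roc_metrics: missing pooled probabilities")
  if (threshold_rule == "youden") {
    cand <- sort(unique(s$prob))
    j <- vapply(cand, function(th) {
      pred <- s$prob >= th
      sum(pred & s$label == "B") / sum(s$label == "B") +
        sum(!pred & s$label == "A") / sum(s$label == "A") - 1
    }, numeric(1))
    threshold <- cand[which.max(j)]   # which.max takes the first (smallest) tie
  }
  pred <- s$prob >= threshold
  tp <- sum(pred & s$label == "B");  fn <- sum(!pred & s$label == "B")
  tn <- sum(!pred & s$label == "A"); fp <- sum(pred & s$label == "A")
  report$auc <- roc_auc(s$prob, s$label)
  report$sensitivity <- tp / (tp + fn)
  report$specificity <- tn / (tn + fp)
  report$ppv <- if (tp + fp > 0) tp / (tp + fp) else NaN
  report$npv <- if (tn + fn > 0) tn / (tn + fn) else NaN
  report$threshold <- threshold
  report$threshold_rule <- threshold_rule
  report
}

#' ROC curve points of a report
#'
#' @param report A `roc_report`.
#' @return Data frame of (`threshold`, `fpr`, `tpr`) sorted from the (0, 0)
#'   to the (1, 1) corner.
#' @export
roc_points <- function(report) {
  s <- report$samples
  th <- c(Inf, sort(unique(s$prob), decreasing = TRUE))
  pts <- t(vapply(th, function(t0) {
    pred <- s$prob >= t0
    c(fpr = sum(pred & s$label == "A") / sum(s$label == "A"),
      tpr = sum(pred & s$label == "B") / sum(s$label == "B"))
  }, numeric(2)))
  data.frame(threshold = th, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

#' @export
print.roc_report <- function(x, ...) {
  cat(sprintf("Cross-validated ROC report: %d subjects (%d cases)\n",
              nrow(x$samples), sum(x$samples$label == "B")))
  if (!is.null(x$auc))
    cat(sprintf("AUC %.3f | sens %.3f | spec %.3f | PPV %.3f | NPV %.3f (threshold %.3g, %s)\n",
                x$auc, x$sensitivity, x$specificity, x$ppv, x$npv,
                x$threshold, x$threshold_rule))
  else cat("Metrics not yet computed; see roc_metrics()\n")
  invisible(x)
}

#' @param x A `roc_report`.
#' @param ... Passed to [graphics::plot()].
#' @rdname roc_metrics
#' @export
plot.roc_report <- function(x, ...) {
  pts <- roc_points(x)
  graphics::plot(pts$fpr, pts$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  if (!is.null(x$auc))
    graphics::legend("bottomright", sprintf("AUC = %.3f", x$auc), bty = "n")
  invisible(x)
}
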