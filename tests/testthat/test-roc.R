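test_that("region-mean features match hand arithmetic", {
  grid <- c(6, 6, 6)
  vols <- array(0, c(grid, 4))
  for (s in 1:4) vols[, , , s] <- s / 10
  vols[1, 1, 1, ] <- c(1, 2, 3, 4)
  vols[2, 1, 1, ] <- c(5, 6, 7, 8)
  cohort <- make_cohort(vols)
  # two clusters: a 2-voxel one and a 1-voxel one, built via a p map
  p <- array(1, grid)
  p[1, 1, 1] <- p[2, 1, 1] <- 1e-5
  p[5, 5, 5] <- 1e-5
  tab <- extract_clusters(p, 0.001, 0, connectivity = 26, peak_map = -p)
  expect_equal(nrow(tab), 2L)
  fm <- region_mean_features(cohort, tab)
  expect_equal(ncol(fm$x), 2L)
  two_vox <- (c(1, 2, 3, 4) + c(5, 6, 7, 8)) / 2
  one_vox <- c(1, 2, 3, 4) / 10
  # columns are in table order (largest cluster first)
  expect_equal(unname(fm$x[, 1]), two_vox)
  expect_equal(unname(fm$x[, 2]), one_vox)
  # constant volume -> constant feature
  vconst <- array(0.42, c(grid, 4))
  fconst <- region_mean_features(make_cohort(vconst), tab)
  expect_true(all(fconst$x == 0.42))
})

test_that("rank AUC equals the brute-force pairwise oracle, including ties", {
  set.seed(55)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    labels <- sample(rep(c("A", "B"), c(ceiling(n / 2), floor(n / 2))))
    prob <- round(runif(n), 1)          # coarse grid forces ties
    expect_equal(roc_auc(prob, labels), oracle_auc(prob, labels))
  }
  # 6-subject hand example
  prob <- c(0.9, 0.8, 0.5, 0.5, 0.2, 0.1)
  labels <- c("B", "B", "B", "A", "A", "A")
  expect_equal(roc_auc(prob, labels), oracle_auc(prob, labels))
  expect_equal(roc_auc(prob, labels), (3 + 3 + 2.5) / 9)
  # degenerate ties: all scores identical -> 0.5
  expect_equal(roc_auc(rep(0.3, 8), rep(c("A", "B"), 4)), 0.5)
  # relabeling symmetry: AUC -> 1 - AUC
  flipped <- ifelse(labels == "A", "B", "A")
  expect_equal(roc_auc(prob, flipped), 1 - roc_auc(prob, labels))
})

test_that("rank AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(66)
  prob <- runif(40)
  labels <- sample(rep(c("A", "B"), 20))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, prob, levels = c("A", "B"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(prob, labels), ref)
})

test_that("operating-point metrics and threshold rules are correct", {
  rep0 <- structure(list(samples = data.frame(
    id = 1:4, label = c("B", "B", "A", "A"), prob = c(0.9, 0.8, 0.1, 0.2),
    fold = 1L)), class = "roc_report")
  m <- roc_metrics(rep0)
  expect_equal(m$auc, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$ppv, 1)
  expect_equal(m$npv, 1)
  # mixed case at threshold 0.5
  rep1 <- structure(list(samples = data.frame(
    id = 1:6, label = c("B", "B", "B", "A", "A", "A"),
    prob = c(0.9, 0.6, 0.3, 0.7, 0.2, 0.1), fold = 1L)), class = "roc_report")
  m1 <- roc_metrics(rep1)
  expect_equal(m1$sensitivity, 2 / 3)
  expect_equal(m1$specificity, 2 / 3)
  expect_equal(m1$ppv, 2 / 3)
  expect_equal(m1$npv, 2 / 3)
  # youden picks a data-dependent threshold; relabel symmetry of sens/spec
  my <- roc_metrics(rep1, threshold_rule = "youden")
  expect_gte(my$sensitivity + my$specificity, m1$sensitivity + m1$specificity)
  rep_fl <- rep1
  rep_fl$samples$label <- ifelse(rep1$samples$label == "A", "B", "A")
  rep_fl$samples$prob <- 1 - rep1$samples$prob
  m_fl <- roc_metrics(rep_fl)
  expect_equal(m_fl$auc, m1$auc)
  # single-class labels are rejected
  rep_bad <- rep1
  rep_bad$samples$label <- "B"
  expect_error(roc_metrics(rep_bad), "both classes")
})

test_that("cross-validated probabilities are deterministic, leak-free and sane", {
  set.seed(77)
  n <- 30
  x <- matrix(rnorm(n * 2), n, 2)
  labels <- rep(c("A", "B"), each = n / 2)
  x[labels == "B", 1] <- x[labels == "B", 1] + 6   # perfectly separable
  r1 <- cv_predicted_probabilities(x, labels, folds = 5, seed = 4)
  r2 <- cv_predicted_probabilities(x, labels, folds = 5, seed = 4)
  expect_identical(r1$samples$prob, r2$samples$prob)
  expect_identical(r1$samples$fold, r2$samples$fold)
  expect_false(anyNA(r1$samples$prob))               # each subject predicted once
  expect_equal(roc_metrics(r1)$auc, 1)
  # too few members per class for the fold count
  expect_error(cv_predicted_probabilities(x[c(1:3, 16:18), ], labels[c(1:3, 16:18)],
                                          folds = 5), "fewer folds")
})

test_that("label permutation drives cross-validated AUC to chance", {
  set.seed(88)
  n <- 24
  x <- matrix(rnorm(n * 3), n, 3)
  x[, 1] <- x[, 1] + rep(c(0, 2), each = n / 2)
  labels <- rep(c("A", "B"), each = n / 2)
  aucs <- vapply(1:50, function(r) {
    perm <- sample(labels)
    rep <- cv_predicted_probabilities(x, perm, folds = 4, seed = r,
                                      c_grid = c(0.1, 10))
    roc_auc(rep$samples$prob, perm)
  }, numeric(1))
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-9)
})
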