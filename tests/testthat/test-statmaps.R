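test_that("binomial conversion matches exact enumeration and identities", {
  # all-correct tail at n = 4: P(X >= 4) = 1/16
  expect_equal(accuracy_to_pvalue(1, 4), 1 / 16)
  # symmetric midpoint of Binomial(65, 1/2): P(X >= 33) = 1/2 exactly
  expect_identical(accuracy_to_pvalue(33 / 65, 65), 0.5)
  # arbitrary-precision enumeration of P(X >= 53 | 65, 1/2), frozen:
  # 2569847592241 / 2^64 computed with exact rational arithmetic
  expect_equal(accuracy_to_pvalue(0.81, 65), 1.3931171712321675e-07,
               tolerance = 1e-12)

  for (n in 1:20) {
    k <- 0:n
    expect_equal(accuracy_to_pvalue(k / n, n),
                 vapply(k, oracle_binom_upper, numeric(1), n = n),
                 tolerance = 1e-12)
    expect_equal(accuracy_to_pvalue(k / n, n, chance = 37 / 65),
                 vapply(k, oracle_binom_upper, numeric(1), n = n, chance = 37 / 65),
                 tolerance = 1e-12)
  }
  expect_error(accuracy_to_pvalue(1.2, 10), "\\[0, 1\\]")
  expect_error(accuracy_to_pvalue(0.5, 10, chance = 1), "chance")
})

test_that("p-value maps are monotone transforms that propagate NaN", {
  acc <- array(sample(0:10, 5^3, replace = TRUE) / 10, c(5, 5, 5))
  acc[2, 3, 4] <- NaN
  pm <- pvalue_map(acc, n = 10)
  expect_true(is.nan(pm$p[2, 3, 4]))
  ok <- !is.na(acc)
  ord <- order(acc[ok])
  expect_true(all(diff(pm$p[ok][ord]) <= 1e-15))   # non-increasing in accuracy
  # constant 0.5 accuracy at odd n maps to a constant 0.5 p map
  pm2 <- pvalue_map(array(0.5, c(3, 3, 3)), n = 9)  # k = round(4.5) = 5 = (9+1)/2
  expect_true(all(pm2$p == 0.5))
})

test_that("connected-component labels match the propagation oracle", {
  set.seed(33)
  for (rep in 1:10) {
    mask <- array(runif(20^3) < 0.25 + 0.05 * rep, c(20, 20, 20))
    for (conn in c(6L, 18L, 26L)) {
      got <- label_components(mask, conn)
      want <- oracle_label_components(mask, conn)
      expect_identical(got, want)
    }
  }
})

test_that("cluster extraction applies strict thresholds and reports peaks", {
  grid <- c(12, 12, 12)
  p <- array(0.9, grid)
  blob1 <- as.matrix(expand.grid(i = 2:6, j = 2:5, k = 2:4))      # 60 voxels
  blob2 <- as.matrix(expand.grid(i = 9:10, j = 9:10, k = 9:11))[1:10, , drop = FALSE]
  p[blob1] <- 1e-4
  p[blob2] <- 1e-4
  peak <- array(0, grid)
  peak[4, 3, 3] <- 0.95
  tab <- extract_clusters(p, p_threshold = 0.001, min_cluster_size = 50,
                          connectivity = 26, peak_map = peak)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$size_voxels, 60L)
  expect_equal(c(tab$peak_i, tab$peak_j, tab$peak_k), c(4, 3, 3))
  expect_equal(tab$peak_value, 0.95)
  # strictness: a 50-voxel cluster does not pass "more than 50"
  p50 <- array(0.9, grid)
  p50[as.matrix(expand.grid(i = 2:6, j = 2:6, k = 2:3))] <- 1e-4  # exactly 50
  expect_equal(nrow(extract_clusters(p50, 0.001, 50)), 0L)
  expect_equal(nrow(extract_clusters(p50, 0.001, 49)), 1L)
  # empty suprathreshold set
  expect_equal(nrow(extract_clusters(array(0.5, grid), 0.001, 10)), 0L)
  expect_error(extract_clusters(p, p_threshold = 0), "p_threshold")
})

test_that("cluster sizes are conserved and ordering is deterministic", {
  set.seed(8)
  p <- array(runif(15^3), c(15, 15, 15))
  tab <- extract_clusters(p, p_threshold = 0.2, min_cluster_size = 3,
                          connectivity = 6, peak_map = -p)
  supra <- sum(p < 0.2)
  labels_all <- label_components(p < 0.2, 6L)
  all_sizes <- tabulate(labels_all[labels_all > 0])
  expect_equal(sum(tab$size_voxels) + sum(all_sizes[all_sizes <= 3]), supra)
  expect_true(all(diff(tab$size_voxels) <= 0))
  # with equal sizes, order falls back to peak linear index
  ties <- which(tab$size_voxels %in% tab$size_voxels[duplicated(tab$size_voxels)])
  if (length(ties) > 1) {
    for (s in unique(tab$size_voxels[ties])) {
      rows <- tab[tab$size_voxels == s, ]
      lin <- rows$peak_i + 15 * (rows$peak_j - 1) + 225 * (rows$peak_k - 1)
      expect_true(all(diff(lin) > 0))
    }
  }
  # label attribute matches table ids
  labs <- attr(tab, "labels")
  for (r in seq_len(nrow(tab)))
    expect_equal(sum(labs == tab$id[r]), tab$size_voxels[r])
})
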