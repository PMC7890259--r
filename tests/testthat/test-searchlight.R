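test_that("cube features follow the documented scan order and edge contract", {
  grid <- c(6, 6, 6)
  n <- 4
  vols <- array(0, c(grid, n))
  for (s in 1:n) vols[, , , s] <- array(seq_len(prod(grid)) + 1000 * s, grid)
  cohort <- make_cohort(vols)

  # interior voxel: 27 columns, first axis fastest
  fm <- extract_cube_features(cohort, c(3, 4, 5))
  expect_equal(ncol(fm$x), 27L)
  expect_equal(fm$in_mask_fraction, 1)
  hand <- c()
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1)
    hand <- c(hand, (3 + di) + 6 * (4 + dj - 1) + 36 * (5 + dk - 1))
  expect_equal(unname(fm$x[2, ]), hand + 2000)

  # cube_edge = 1 reduces to the center voxel value
  fm1 <- extract_cube_features(cohort, c(3, 4, 5), cube_edge = 1L)
  expect_equal(ncol(fm1$x), 1L)
  expect_equal(unname(fm1$x[, 1]), vols[3, 4, 5, ])

  # corner: 8 in-grid voxels, the rest imputed as 0, verified by hand enumeration
  fmc <- extract_cube_features(cohort, c(1, 1, 1))
  expect_equal(ncol(fmc$x), 27L)
  expect_equal(fmc$in_mask_fraction, 8 / 27)
  nonzero <- which(fmc$x[1, ] != 0)
  hand_cols <- c()
  col <- 0L
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    col <- col + 1L
    if (1 + di >= 1 && 1 + dj >= 1 && 1 + dk >= 1) hand_cols <- c(hand_cols, col)
  }
  expect_equal(nonzero, hand_cols)

  # out-of-mask center errors
  cohort$mask[2, 2, 2] <- FALSE
  expect_error(extract_cube_features(cohort, c(2, 2, 2)), "mask")
})

test_that("perfect separation in the cube yields accuracy 1 and chance data do not", {
  set.seed(7)
  grid <- c(7, 7, 7)
  n <- 12
  vols <- array(0.5 + rnorm(prod(grid) * n, 0, 0.02), c(grid, n))
  vols[4, 4, 4, 7:12] <- vols[4, 4, 4, 7:12] + 1   # huge one-voxel effect for group B
  cohort <- make_cohort(vols, groups = rep(c("A", "B"), each = 6))
  cfg <- searchlight_config(c_grid = c(0.1, 1, 10), seed = 2)
  acc <- loo_accuracy_at_voxel(extract_cube_features(cohort, c(4, 4, 4)), cfg,
                               voxel_index = 171)
  expect_equal(acc, 1)
})

test_that("label permutation destroys above-chance accuracy", {
  set.seed(41)
  n <- 40
  x <- matrix(rnorm(n * 27), n, 27)
  x[, 14] <- x[, 14] + rep(c(0, 3), each = n / 2)
  labels <- rep(c("A", "B"), each = n / 2)
  cfg <- searchlight_config(c_grid = c(0.1, 10), inner_folds = 5, seed = 9)
  accs <- vapply(1:50, function(r) {
    perm <- sample(labels)
    loo_accuracy_at_voxel(x, cfg, labels = perm, voxel_index = r)
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  # no information => expected accuracy at or below chance (LOO is pessimistic
  # on null data because training sets are tilted against the held-out class)
  expect_lt(mean(accs), 0.5 + 3 * se)
  # and the real labels do carry signal
  real <- loo_accuracy_at_voxel(x, cfg, labels = labels, voxel_index = 0)
  expect_gt(real, 0.7)
})

test_that("map accuracies are exact multiples of 1/n and match the standalone path", {
  cohort <- noise_cohort(grid = c(6, 6, 6), n_a = 5, n_b = 5, seed = 3)
  cfg <- searchlight_config(c_grid = c(0.5, 8), inner_folds = 3, seed = 11)
  sl <- searchlight_map(cohort, cfg)
  a <- sl$accuracy[sl$evaluated]
  expect_true(all(abs(a * 10 - round(a * 10)) < 1e-12))

  v <- c(3, 4, 3)
  vox <- v[1] + 6 * (v[2] - 1) + 36 * (v[3] - 1)
  standalone <- loo_accuracy_at_voxel(extract_cube_features(cohort, v), cfg,
                                      voxel_index = vox)
  expect_identical(sl$accuracy[v[1], v[2], v[3]], standalone)
})

test_that("voxels with too little mask coverage are skipped as NaN", {
  cohort <- noise_cohort(grid = c(8, 8, 8), n_a = 4, n_b = 4, seed = 5)
  cohort$mask[, , 5:8] <- FALSE     # half-space mask
  sl <- searchlight_map(cohort, searchlight_config(c_grid = 1, seed = 1))
  # centers on the mask boundary plane keep >= 18/27 in-mask -> evaluated;
  # corner/edge voxels of the remaining slab fall below 0.5 -> NaN
  expect_true(is.nan(sl$accuracy[1, 1, 1]))     # 8/27 voxels in grid & mask
  expect_false(is.nan(sl$accuracy[4, 4, 4]))    # interior of the slab
  expect_true(all(is.nan(sl$accuracy[, , 5:8])))
})

test_that("mean accuracy in the effect region is non-decreasing in effect size", {
  deltas <- c(0, 0.5, 1, 2) * 0.05
  means <- matrix(NA_real_, 3, length(deltas))
  for (s in 1:3) {
    for (d in seq_along(deltas)) {
      regions <- if (deltas[d] > 0)
        list(effect_region(c(5, 5, 5), delta = -deltas[d], radius = 2)) else list()
      cfg <- synth_config(grid_shape = c(10, 10, 10), n_group_a = 8, n_group_b = 8,
                          effect_regions = regions, noise_sd = 0.05,
                          smooth_fwhm_mm = 1.5, voxel_size_mm = 1.5, seed = 20 + s)
      cohort <- generate_cohort(cfg)
      sl <- searchlight_map(cohort, searchlight_config(c_grid = 1, seed = s))
      region <- true_effect_mask(synth_config(grid_shape = c(10, 10, 10),
                                              effect_regions = list(effect_region(c(5, 5, 5), -1, radius = 2))))
      means[s, d] <- mean(sl$accuracy[region], na.rm = TRUE)
    }
  }
  avg <- colMeans(means)
  expect_true(all(diff(avg) >= -1e-9))
  expect_gt(avg[length(avg)], avg[1])
})
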