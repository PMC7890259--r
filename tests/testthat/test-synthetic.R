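test_that("identical configurations generate bit-identical cohorts", {
  cfg <- synth_config(grid_shape = c(10, 10, 10), n_group_a = 3, n_group_b = 3,
                      smooth_fwhm_mm = 3, seed = 9)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$data, c2$data)
  expect_identical(c1$subjects, c2$subjects)
  c3 <- generate_cohort(synth_config(grid_shape = c(10, 10, 10), n_group_a = 3,
                                     n_group_b = 3, smooth_fwhm_mm = 3, seed = 10))
  expect_false(identical(c1$data, c3$data))
})

test_that("a 37 + 28 configuration yields a 65-row subject table", {
  cfg <- synth_config(grid_shape = c(8, 8, 8), n_group_a = 37, n_group_b = 28,
                      smooth_fwhm_mm = 0, seed = 1)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort$subjects), 65L)
  expect_equal(sum(cohort$subjects$group == "A"), 37L)
  expect_equal(sum(cohort$subjects$group == "B"), 28L)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(synth_config(grid_shape = c(4, 8, 8)), "grid_shape")
  expect_error(synth_config(n_group_a = 1), "n_group_a")
  expect_error(synth_config(noise_sd = 0), "noise_sd")
  expect_error(synth_config(smooth_fwhm_mm = -1), "smooth_fwhm_mm")
  expect_error(synth_config(grid_shape = c(10, 10, 10),
                            effect_regions = list(effect_region(c(10, 10, 10),
                                                                delta = 1, radius = 3))),
               "effect_regions\\[\\[1\\]\\]")
})

test_that("injected group effect converges to delta before smoothing", {
  delta <- -0.12
  cfg <- synth_config(grid_shape = c(10, 10, 10), n_group_a = 100, n_group_b = 100,
                      effect_regions = list(effect_region(c(5, 5, 5), delta = delta,
                                                          radius = 2)),
                      noise_sd = 0.05, smooth_fwhm_mm = 0, seed = 4)
  cohort <- generate_cohort(cfg)
  truth <- true_effect_mask(cfg)
  m <- cohort_matrix(cohort)[, as.vector(truth), drop = FALSE]
  grp <- cohort$subjects$group
  diff_hat <- mean(colMeans(m[grp == "B", ]) - colMeans(m[grp == "A", ]))
  se_single <- cfg$noise_sd * sqrt(1 / 100 + 1 / 100)
  expect_lt(abs(diff_hat - delta), 3 * se_single)
})

test_that("null cohorts give voxel-wise t statistics matching the central t", {
  cfg <- synth_config(grid_shape = c(12, 12, 12), n_group_a = 10, n_group_b = 10,
                      noise_sd = 0.05, smooth_fwhm_mm = 0, seed = 2)
  cohort <- generate_cohort(cfg)
  tm <- voxelwise_ttest(cohort)
  tv <- tm$t[!is.na(tm$t)]
  expect_gte(length(tv), 1000)
  ks <- suppressWarnings(stats::ks.test(tv, stats::pt, df = tm$dof))
  expect_gt(ks$p.value, 0.01)
})

test_that("smoothing honours the kernel contract", {
  v <- array(rnorm(12^3), c(12, 12, 12))
  expect_identical(smooth_volume(v, 0), v)
  expect_error(smooth_volume(v, -2), "fwhm")

  const <- array(3.7, c(10, 10, 10))
  expect_equal(smooth_volume(const, 8, 1.5), const, tolerance = 1e-12)

  # interior spike (at least twice the kernel radius from every boundary):
  # mass preserved, and rendered profile has FWHM = 8/1.5 voxels
  spike <- array(0, c(41, 41, 41))
  spike[21, 21, 21] <- 1
  sm <- smooth_volume(spike, 8, 1.5)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_equal(which.max(sm), which.max(spike))
  prof <- sm[, 21, 21]
  half <- max(prof) / 2
  above <- which(prof >= half)
  # linear interpolation at the half-maximum crossings
  lo <- min(above); hi <- max(above)
  x1 <- lo - 1 + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  x2 <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  expect_equal(x2 - x1, 8 / 1.5, tolerance = 0.25)
})

test_that("true_effect_mask enumerates exactly the nonzero-effect voxels", {
  cfg0 <- synth_config(grid_shape = c(12, 12, 12), smooth_fwhm_mm = 0)
  expect_false(any(true_effect_mask(cfg0)))

  reg <- effect_region(c(6, 6, 6), delta = -0.1, radius = 2)
  cfg1 <- synth_config(grid_shape = c(12, 12, 12), effect_regions = list(reg))
  m <- true_effect_mask(cfg1)
  # brute-force voxel scan of the discrete sphere
  cnt <- 0L
  for (i in 1:12) for (j in 1:12) for (k in 1:12)
    if ((i - 6)^2 + (j - 6)^2 + (k - 6)^2 <= 4) cnt <- cnt + 1L
  expect_equal(sum(m), cnt)

  reg2 <- effect_region(c(10, 10, 10), delta = 0.2, extents = c(3, 3, 3), shape = "cube")
  cfg2 <- synth_config(grid_shape = c(12, 12, 12), effect_regions = list(reg, reg2))
  expect_equal(sum(true_effect_mask(cfg2)), cnt + 27L)

  # zero-delta regions do not count as true effects
  cfg3 <- synth_config(grid_shape = c(12, 12, 12),
                       effect_regions = list(effect_region(c(6, 6, 6), delta = 0, radius = 2)))
  expect_false(any(true_effect_mask(cfg3)))
})

test_that("covariate loadings create and localize an age effect", {
  cfg <- synth_config(grid_shape = c(10, 10, 10), n_group_a = 20, n_group_b = 20,
                      covariate_model = list(age_region = effect_region(c(5, 5, 5), 0, radius = 2),
                                             age_slope = 0.2),
                      noise_sd = 0.05, smooth_fwhm_mm = 0, seed = 6)
  cohort <- generate_cohort(cfg)
  region <- true_effect_mask(synth_config(grid_shape = c(10, 10, 10),
                                          effect_regions = list(effect_region(c(5, 5, 5), 1, radius = 2))))
  m <- cohort_matrix(cohort)
  age_z <- scale(cohort$subjects$age)[, 1]
  in_cor <- mean(abs(cor(age_z, m[, as.vector(region)])))
  out_cor <- mean(abs(cor(age_z, m[, !as.vector(region)])))
  expect_gt(in_cor, 0.8)
  expect_lt(out_cor, 0.5)
})

test_that("dilate_mask and dice_coefficient behave on hand cases", {
  m <- array(FALSE, c(7, 7, 7)); m[4, 4, 4] <- TRUE
  expect_equal(sum(dilate_mask(m, 1)), 27)
  expect_identical(dilate_mask(m, 0), m)
  a <- array(FALSE, c(5, 5, 5)); b <- a
  a[1:3, 1, 1] <- TRUE; b[2:4, 1, 1] <- TRUE
  expect_equal(dice_coefficient(a, b), 2 * 2 / 6)
  expect_true(is.nan(dice_coefficient(a & FALSE, b & FALSE)))
})
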