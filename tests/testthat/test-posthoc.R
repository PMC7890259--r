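test_that("covariate regression matches hand least squares at a single voxel", {
  vols <- array(0, c(8, 8, 8, 6))
  gm <- c(0.52, 0.61, 0.47, 0.58, 0.66, 0.43)
  age <- c(35, 42, 51, 38, 60, 47)
  gender <- c("M", "F", "M", "F", "M", "F")
  for (s in 1:6) vols[, , , s] <- gm[s]
  cohort <- make_cohort(vols, groups = c("A", "A", "A", "B", "B", "B"),
                        ages = age, genders = gender)
  adj <- regress_covariates(cohort)

  X <- cbind(1, age, as.numeric(gender == "M"))
  beta <- solve(t(X) %*% X, t(X) %*% gm)      # normal equations by hand
  res_hand <- gm - as.vector(X %*% beta) + mean(gm)
  expect_equal(adj$data[3, 3, 3, ], res_hand, tolerance = 1e-10)
})

test_that("covariate regression is idempotent and preserves the grand mean", {
  cohort <- noise_cohort(grid = c(7, 7, 7), n_a = 6, n_b = 6, seed = 12)
  adj1 <- regress_covariates(cohort)
  adj2 <- regress_covariates(adj1)
  expect_equal(adj2$data, adj1$data, tolerance = 1e-10)
  m0 <- colMeans(cohort_matrix(cohort))
  m1 <- colMeans(cohort_matrix(adj1))
  expect_equal(m1, m0, tolerance = 1e-12)
})

test_that("rank-deficient nuisance designs are rejected naming the column", {
  cohort <- noise_cohort(n_a = 4, n_b = 4, seed = 2)
  cohort$subjects$copy_age <- cohort$subjects$age
  expect_error(regress_covariates(cohort, c("age", "copy_age")), "copy_age")
  expect_error(regress_covariates(cohort, "ftnd"), "ftnd")
})

test_that("a seeded pure-age effect is neutralized by covariate regression", {
  cfg <- synth_config(grid_shape = c(12, 12, 12), n_group_a = 15, n_group_b = 15,
                      covariate_model = list(age_region = effect_region(c(6, 6, 6), 0, radius = 3),
                                             age_slope = 0.15),
                      noise_sd = 0.05, smooth_fwhm_mm = 3, voxel_size_mm = 1.5,
                      seed = 31)
  cohort <- generate_cohort(cfg)
  t_pre <- voxelwise_ttest(cohort)
  adj <- regress_covariates(cohort)
  t_post <- voxelwise_ttest(adj)
  expect_lt(max(abs(t_post$t), na.rm = TRUE), max(abs(t_pre$t), na.rm = TRUE))
  # residual group contrast is null-like: within the usual extreme range for
  # ~1700 dependent t variates
  expect_lt(max(abs(t_post$t), na.rm = TRUE), 5.5)
})

test_that("voxel-wise t follows the pooled formula and the sign convention", {
  vols <- array(0, c(8, 8, 8, 6))
  a_vals <- c(0.60, 0.55, 0.65)
  b_vals <- c(0.40, 0.45, 0.50)
  for (s in 1:3) vols[, , , s] <- a_vals[s]
  for (s in 4:6) vols[, , , s] <- b_vals[s - 3]
  cohort <- make_cohort(vols, groups = rep(c("A", "B"), each = 3))
  tm <- voxelwise_ttest(cohort)
  sp2 <- (var(a_vals) * 2 + var(b_vals) * 2) / 4
  t_hand <- (mean(a_vals) - mean(b_vals)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(tm$t[4, 4, 4], t_hand, tolerance = 1e-12)
  expect_equal(tm$dof, 4L)
  expect_gt(tm$t[4, 4, 4], 0)                   # B lower => positive t
  # flipping the groups flips the sign exactly
  cohort_fl <- make_cohort(vols, groups = rep(c("B", "A"), each = 3))
  expect_equal(voxelwise_ttest(cohort_fl)$t[4, 4, 4], -t_hand, tolerance = 1e-12)
  # identical group means -> t = 0; zero variance is flagged
  vz <- array(0.5, c(8, 8, 8, 6))
  tz <- voxelwise_ttest(make_cohort(vz, groups = rep(c("A", "B"), each = 3)))
  expect_true(all(tz$t[!is.na(tz$t)] == 0))
  expect_true(all(tz$zero_variance))
})

test_that("permutation FWE returns the formula floor for dominant clusters", {
  cfg <- synth_config(grid_shape = c(10, 10, 10), n_group_a = 12, n_group_b = 12,
                      effect_regions = list(effect_region(c(5, 5, 5), delta = -0.2, radius = 2)),
                      noise_sd = 0.05, smooth_fwhm_mm = 3, voxel_size_mm = 1.5, seed = 17)
  cohort <- generate_cohort(cfg)
  fw <- cluster_fwe_permutation(cohort, n_permutations = 199, seed = 5)
  expect_gt(nrow(fw$clusters), 0)
  top <- fw$clusters[1, ]
  expect_true(top$surviving)
  expect_equal(top$p_fwe, 1 / 200)              # larger than every null max
  expect_true(all(fw$clusters$p_fwe >= 1 / 200 & fw$clusters$p_fwe <= 1))
  # the recovered cluster sits on the seeded region
  truth <- true_effect_mask(cfg)
  labs <- attr(fw$clusters, "labels")
  expect_gt(sum(labs == top$id & truth) / sum(truth), 0.5)
})

test_that("permutation FWE validates its inputs", {
  cohort <- noise_cohort(n_a = 3, n_b = 3, seed = 3)
  expect_error(cluster_fwe_permutation(cohort, n_permutations = 50), "100")
  expect_error(cluster_fwe_permutation(cohort, n_permutations = 999), "distinct relabelings")
})
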