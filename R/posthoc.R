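#' Remove nuisance covariate effects from a cohort
#'
#' Fits, at every voxel, a least-squares model of GM on an intercept plus the
#' requested covariates, pooling both groups, and subtracts the fitted
#' covariate effects.  Group membership is deliberately excluded from the
#' nuisance model so that group structure survives the adjustment.  The
#' returned volumes are the residuals plus the voxel-wise grand mean, and the
#' operation is idempotent.
#'
#' `gender` is coded 0/1 (`F`/`M`); `age` is used as given (centering is
#' absorbed by the intercept).
#'
#' @param cohort A [cohort_volumes()] object.
#' @param covariates Character vector of subject-table columns (default
#'   `c("age", "gender")`).
#' @return A `cohort_volumes` object of adjusted volumes (values may be
#'   slightly negative after adjustment).
#' @export
regress_covariates <- function(cohort, covariates = c("age", "gender")) {
  missing_cov <- setdiff(covariates, names(cohort$subjects))
  if (length(missing_cov))
    stopf("regress_covariates: covariate(s) not in subject table: %s",
          paste(missing_cov, collapse = ", "))
  X <- nuisance_design(cohort$subjects, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("regress_covariates: design is rank-deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  Y <- cohort_matrix(cohort)
  fitted <- X %*% qr.coef(qx, Y)
  resid <- Y - fitted
  adj <- sweep(resid, 2, colMeans(Y), `+`)
  d <- dim(cohort$data)
  cohort_volumes(array(t(adj), d), cohort$mask, cohort$affine, cohort$subjects,
                 check_nonnegative = FALSE)
}

nuisance_design <- function(subjects, covariates) {
  cols <- list(intercept = rep(1, nrow(subjects)))
  for (cv in covariates) {
    v <- subjects[[cv]]
    if (cv == "gender" || is.character(v) || is.factor(v)) {
      v <- as.character(v)
      lev <- sort(unique(v))
      if (length(lev) > 2L)
        stopf("covariate '%s' has more than two levels", cv)
      cols[[cv]] <- as.numeric(v == lev[length(lev)])
    } else cols[[cv]] <- as.numeric(v)
  }
  do.call(cbind, cols)
}

#' Voxel-wise two-sample t-test between groups
#'
#' Pooled-variance two-sample t statistics at every in-mask voxel, with the
#' case-control sign convention: `t = (mean_A - mean_B) / SE`, so a positive
#' t means lower GM in the case group (`B`).  Voxels with zero pooled
#' variance get `t = 0` and are flagged.
#'
#' @param cohort A [cohort_volumes()] object.
#' @param analysis_mask Optional logical 3D array restricting the test
#'   (defaults to the cohort mask).
#' @return Object of class `t_map`: list with `t` (3D array, `NaN` outside the
#'   analysis mask), `dof` (`n - 2`), `n`, and `zero_variance` (logical 3D
#'   array flagging degenerate voxels).
#' @export
voxelwise_ttest <- function(cohort, analysis_mask = NULL) {
  if (is.null(analysis_mask)) analysis_mask <- cohort$mask
  if (!identical(dim(analysis_mask), grid_shape(cohort)))
    stopf("voxelwise_ttest: 'analysis_mask' grid does not match the cohort")
  if (!any(analysis_mask)) stopf("voxelwise_ttest: empty analysis mask")
  Y <- cohort_matrix(cohort)[, as.vector(analysis_mask), drop = FALSE]
  grp <- cohort$subjects$group
  res <- two_sample_t(Y, grp == "A")
  grid <- grid_shape(cohort)
  tmap <- array(NaN, grid)
  tmap[analysis_mask] <- res$t
  zv <- array(FALSE, grid)
  zv[analysis_mask] <- res$zero_variance
  structure(list(t = tmap, dof = res$dof, n = length(grp), zero_variance = zv),
            class = "t_map")
}

# Vectorized pooled-variance two-sample t over the columns of Y.
# is_a: logical, TRUE for the control group (A).  t > 0 <=> mean_A > mean_B.
two_sample_t <- function(Y, is_a) {
  na <- sum(is_a); nb <- sum(!is_a)
  sa <- colSums(Y[is_a, , drop = FALSE]);  qa <- colSums(Y[is_a, , drop = FALSE]^2)
  sb <- colSums(Y[!is_a, , drop = FALSE]); qb <- colSums(Y[!is_a, , drop = FALSE]^2)
  ma <- sa / na; mb <- sb / nb
  ssa <- qa - na * ma^2; ssb <- qb - nb * mb^2
  sp2 <- (ssa + ssb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (ma - mb) / se
  zero <- !is.na(se) & se <= 0
  tt[zero] <- 0
  list(t = tt, dof = na + nb - 2L, zero_variance = zero)
}

#' @export
print.t_map <- function(x, ...) {
  v <- x$t[!is.na(x$t)]
  cat(sprintf("Voxel-wise t map (dof = %d, n = %d): %d voxels, t range %.3f to %.3f\n",
              x$dof, x$n, length(v), min(v), max(v)))
  cat("Sign convention: positive t = lower GM in group B (cases)\n")
  if (any(x$zero_variance)) cat(sprintf("%d voxel(s) had zero pooled variance (t set to 0)\n",
                                        sum(x$zero_variance)))
  invisible(x)
}

#' Two-tailed p-values of a t map
#'
#' @param t_map A `t_map` object.
#' @return 3D array of two-tailed p-values (`NaN` outside the analysis mask).
#' @export
t_map_pvalues <- function(t_map) {
  array(2 * pt(abs(t_map$t), t_map$dof, lower.tail = FALSE), dim(t_map$t))
}

#' Cluster-level family-wise-error control by label permutation
#'
#' Forms clusters of the observed group contrast at the two-tailed
#' cluster-forming threshold (`|t| > t_crit` with
#' `t_crit = qt(1 - cluster_forming_p / 2, dof)`), then builds the null
#' distribution of the maximum cluster extent by recomputing the t map under
#' `n_permutations` random relabelings of the group assignment.  The corrected
#' p-value of an observed cluster of size `s` is
#' `(1 + #\{null max >= s\}) / (n_permutations + 1)`; clusters with corrected
#' `p < fwe_p` are marked surviving.
#'
#' Covariates are not re-regressed inside the permutation loop: adjust the
#' cohort once with [regress_covariates()] beforehand and permute the labels
#' of the adjusted data (a Freedman-Lane-style scheme).
#'
#' @param cohort A [cohort_volumes()] object (typically covariate-adjusted).
#' @param analysis_mask Optional logical 3D array (defaults to the cohort
#'   mask); for a post hoc analysis pass the MVPA cluster mask
#'   ([cluster_mask()]).
#' @param cluster_forming_p Two-tailed voxel-level threshold forming clusters.
#' @param connectivity 6, 18 or 26.
#' @param n_permutations Number of relabelings (>= 100).
#' @param fwe_p Family-wise significance level for the surviving flag.
#' @param seed RNG seed for the relabelings.
#' @return Object of class `fwe_result`: list with `clusters` (a
#'   `cluster_table` with extra columns `p_fwe` and `surviving`), `t_map`,
#'   `t_crit`, `null_max_sizes` and `n_permutations`.
#' @export
cluster_fwe_permutation <- function(cohort, analysis_mask = NULL,
                                    cluster_forming_p = 0.001,
                                    connectivity = 26L,
                                    n_permutations = 999L, fwe_p = 0.05,
                                    seed = 1L) {
  if (!is_count(n_permutations, 100L))
    stopf("cluster_fwe_permutation: 'n_permutations' must be an integer >= 100")
  if (is.null(analysis_mask)) analysis_mask <- cohort$mask
  grp <- cohort$subjects$group
  n <- length(grp)
  n_distinct <- exp(lchoose(n, sum(grp == "A")))
  if (n_distinct < n_permutations)
    stopf("cluster_fwe_permutation: only %.0f distinct relabelings exist for %d permutations",
          n_distinct, n_permutations)

  tmap <- voxelwise_ttest(cohort, analysis_mask)
  t_crit <- qt(1 - cluster_forming_p / 2, tmap$dof)
  grid <- grid_shape(cohort)
  obs_mask <- !is.na(tmap$t) & abs(tmap$t) > t_crit
  clusters <- clusters_from_mask(obs_mask, 0L, connectivity,
                                 peak_map = tmap$t, affine = cohort$affine,
                                 peak_by_abs = TRUE)

  Y <- cohort_matrix(cohort)[, as.vector(analysis_mask), drop = FALSE]
  Y2 <- Y^2
  maskv <- as.vector(analysis_mask)
  null_max <- with_local_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      perm_a <- logical(n)
      perm_a[sample.int(n, sum(grp == "A"))] <- TRUE
      tt <- perm_t(Y, Y2, perm_a)
      supra <- abs(tt) > t_crit
      if (!any(supra)) return(0L)
      m3 <- array(FALSE, grid)
      m3[maskv] <- supra
      lab <- label_components(m3, connectivity)
      max(tabulate(lab[lab > 0]))
    }, integer(1))
  })

  p_fwe <- vapply(clusters$size_voxels, function(s)
    (1 + sum(null_max >= s)) / (n_permutations + 1), numeric(1))
  clusters$p_fwe <- p_fwe
  clusters$surviving <- p_fwe < fwe_p
  structure(list(clusters = clusters, t_map = tmap, t_crit = t_crit,
                 null_max_sizes = null_max, n_permutations = n_permutations,
                 fwe_p = fwe_p),
            class = "fwe_result")
}

# t statistic under a permuted group-A indicator, using precomputed squares.
perm_t <- function(Y, Y2, is_a) {
  na <- sum(is_a); nb <- nrow(Y) - na
  sa <- colSums(Y[is_a, , drop = FALSE]);  qa <- colSums(Y2[is_a, , drop = FALSE])
  sb <- colSums(Y) - sa;                   qb <- colSums(Y2) - qa
  ma <- sa / na; mb <- sb / nb
  sp2 <- (qa - na * ma^2 + qb - nb * mb^2) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (ma - mb) / se
  tt[!is.na(se) & se <= 0] <- 0
  tt
}

#' @export
print.fwe_result <- function(x, ...) {
  cat(sprintf("Permutation cluster-FWE (%d permutations, |t| > %.3f):\n",
              x$n_permutations, x$t_crit))
  if (nrow(x$clusters) == 0L) {
    cat("no suprathreshold clusters\n")
  } else {
    df <- as.data.frame(x$clusters)[, c("id", "size_voxels", "peak_value", "p_fwe", "surviving")]
    print(df, digits = 4)
    cat(sprintf("%d cluster(s) surviving at FWE p < %.3g\n",
                sum(x$clusters$surviving), x$fwe_p))
  }
  invisible(x)
}
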