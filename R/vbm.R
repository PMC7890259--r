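#' Configure the whole-brain VBM contrast
#'
#' @param cluster_forming_p Two-tailed voxel-level threshold for cluster
#'   formation (default 0.001).
#' @param min_cluster_size Minimum cluster extent; clusters must exceed it
#'   (default 50 voxels).
#' @param covariates Nuisance covariates entered into the voxel-wise GLM.
#' @param connectivity 6, 18 or 26.
#' @return Object of class `vbm_config`.
#' @export
vbm_config <- function(cluster_forming_p = 0.001, min_cluster_size = 50L,
                       covariates = c("age", "gender"), connectivity = 26L) {
  if (cluster_forming_p <= 0 || cluster_forming_p >= 1)
    stopf("vbm_config: 'cluster_forming_p' must be in (0, 1)")
  if (!is_count(min_cluster_size, 0L))
    stopf("vbm_config: 'min_cluster_size' must be a non-negative integer")
  if (!connectivity %in% c(6L, 18L, 26L))
    stopf("vbm_config: 'connectivity' must be 6, 18 or 26")
  structure(list(cluster_forming_p = cluster_forming_p,
                 min_cluster_size = as.integer(min_cluster_size),
                 covariates = covariates, connectivity = as.integer(connectivity)),
            class = "vbm_config")
}

#' Whole-brain voxel-wise GLM group contrast
#'
#' At every in-mask voxel fits `GM ~ intercept + group + covariates` by least
#' squares and returns the t statistic of the group contrast, signed so that
#' a positive t means lower GM in the case group (`B`) after covariate
#' adjustment.  Residual degrees of freedom are `n` minus the number of model
#' columns.
#'
#' @param cohort A [cohort_volumes()] object.
#' @param config A [vbm_config()].
#' @return A `t_map` object (see [voxelwise_ttest()]).
#' @export
wholebrain_tmap <- function(cohort, config = vbm_config()) {
  subjects <- cohort$subjects
  X <- nuisance_design(subjects, config$covariates)
  X <- cbind(X[, "intercept", drop = FALSE],
             group_b = as.numeric(subjects$group == "B"),
             X[, setdiff(colnames(X), "intercept"), drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("wholebrain_tmap: rank-deficient design; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  maskv <- as.vector(cohort$mask)
  Y <- cohort_matrix(cohort)[, maskv, drop = FALSE]
  n <- nrow(Y); p <- ncol(X)
  beta <- qr.coef(qx, Y)
  resid <- Y - X %*% beta
  rss <- colSums(resid^2)
  dof <- n - p
  xtx_inv <- chol2inv(qr.R(qx))
  gi <- match("group_b", colnames(X))
  se <- sqrt(rss / dof * xtx_inv[gi, gi])
  tt <- -beta[gi, ] / se           # positive t <=> case group (B) lower
  zero <- !is.na(se) & se <= 0
  tt[zero] <- 0

  grid <- grid_shape(cohort)
  tmap <- array(NaN, grid)
  tmap[cohort$mask] <- tt
  zv <- array(FALSE, grid)
  zv[cohort$mask] <- zero
  structure(list(t = tmap, dof = dof, n = n, zero_variance = zv),
            class = "t_map")
}

#' Signed cluster tables of a VBM t map
#'
#' Clusters are formed separately on `t > t_crit` (case group lower:
#' GM decrease in group B) and `t < -t_crit` (case group higher), where
#' `t_crit` is the two-tailed `cluster_forming_p` quantile of the t
#' distribution at the map's degrees of freedom.  Both tables apply the
#' `min_cluster_size` filter and locate peaks by `|t|`.
#'
#' @param t_map A `t_map` (from [wholebrain_tmap()]).
#' @param config A [vbm_config()].
#' @param affine Optional affine for peak world coordinates.
#' @return Object of class `vbm_clusters`: list with `case_lower` and
#'   `case_higher` cluster tables and `t_crit`.
#' @export
vbm_clusters <- function(t_map, config = vbm_config(), affine = NULL) {
  t_crit <- qt(1 - config$cluster_forming_p / 2, t_map$dof)
  tt <- t_map$t
  pos <- !is.na(tt) & tt > t_crit
  neg <- !is.na(tt) & tt < -t_crit
  structure(list(
    case_lower = clusters_from_mask(pos, config$min_cluster_size,
                                    config$connectivity, peak_map = tt,
                                    affine = affine, peak_by_abs = TRUE),
    case_higher = clusters_from_mask(neg, config$min_cluster_size,
                                     config$connectivity, peak_map = tt,
                                     affine = affine, peak_by_abs = TRUE),
    t_crit = t_crit), class = "vbm_clusters")
}

#' @export
print.vbm_clusters <- function(x, ...) {
  cat(sprintf("VBM clusters (|t| > %.3f):\n", x$t_crit))
  cat("Case group lower (t > 0):\n"); print(x$case_lower)
  cat("Case group higher (t < 0):\n"); print(x$case_higher)
  invisible(x)
}
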