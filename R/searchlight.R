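#' Configure the searchlight classifier
#'
#' Settings for the cube searchlight: neighbourhood size, SVM kernel,
#' hyperparameter grids for the nested cross-validation, and edge handling.
#'
#' The default kernel is linear, in which case `g_grid` is ignored and the
#' nested grid search runs over `c_grid` only.  An `"rbf"` mode tunes
#' `(C, gamma)` jointly.  Grids follow the usual LIBSVM-style log-2 spacing.
#' Inner folds are stratified by class, and inner-CV ties are broken
#' deterministically: highest inner accuracy, then smallest `C`, then smallest
#' `gamma`.
#'
#' @param cube_edge Odd integer edge length of the searchlight cube (default 3,
#'   i.e. 27 voxels).
#' @param kernel `"linear"` or `"rbf"`.
#' @param c_grid Positive regularization constants to search.
#' @param g_grid Positive RBF widths to search (`"rbf"` only).
#' @param inner_folds Folds of the nested cross-validation (>= 2).
#' @param min_in_mask_fraction Minimum fraction of the cube that must lie
#'   inside the mask for a center voxel to be evaluated; below it the voxel is
#'   skipped (`NaN`).  Cube voxels outside the grid or mask are imputed as 0
#'   (background GM).
#' @param standardize Standardize feature columns (center/scale over all
#'   subjects) before classification.  Off by default: GM values are fed to
#'   the classifier raw.
#' @param seed Seed for inner-fold shuffling; each voxel derives its own
#'   stream from `(seed, voxel index)`, so maps are independent of evaluation
#'   order.
#' @return An object of class `searchlight_config`.
#' @export
searchlight_config <- function(cube_edge = 3L, kernel = c("linear", "rbf"),
                               c_grid = 2^seq(-5, 9, by = 2),
                               g_grid = 2^seq(-9, 3, by = 2),
                               inner_folds = 5L, min_in_mask_fraction = 0.5,
                               standardize = FALSE, seed = 1L) {
  kernel <- match.arg(kernel)
  if (!is_count(cube_edge) || cube_edge %% 2 == 0)
    stopf("searchlight_config: 'cube_edge' must be an odd positive integer")
  if (!is_count(inner_folds, 2L)) stopf("searchlight_config: 'inner_folds' must be >= 2")
  if (length(c_grid) < 1L || any(c_grid <= 0)) stopf("searchlight_config: 'c_grid' must be positive")
  if (length(g_grid) < 1L || any(g_grid <= 0)) stopf("searchlight_config: 'g_grid' must be positive")
  if (min_in_mask_fraction < 0 || min_in_mask_fraction > 1)
    stopf("searchlight_config: 'min_in_mask_fraction' must be in [0, 1]")
  structure(list(cube_edge = as.integer(cube_edge), kernel = kernel,
                 c_grid = sort(as.numeric(c_grid)), g_grid = sort(as.numeric(g_grid)),
                 inner_folds = as.integer(inner_folds),
                 min_in_mask_fraction = min_in_mask_fraction,
                 standardize = isTRUE(standardize), seed = as.integer(seed)),
            class = "searchlight_config")
}

# Cube offsets in the documented scan order: first axis fastest (column-major),
# matching R's linear indexing of the volume.
cube_offsets <- function(cube_edge) {
  r <- (cube_edge - 1L) / 2L
  as.matrix(expand.grid(di = -r:r, dj = -r:r, dk = -r:r))
}

#' Extract cube-neighbourhood features at a voxel
#'
#' Builds the subjects-by-voxels feature matrix for the searchlight cube
#' centered at `center`: one row per subject, one column per cube voxel in
#' column-major scan order (first axis fastest).  Cube voxels outside the grid
#' or outside the mask contribute 0 (background GM).
#'
#' @param cohort A [cohort_volumes()] object.
#' @param center Voxel coordinates (length-3, 1-based); must be inside the
#'   mask.
#' @param cube_edge Odd cube edge length.
#' @return An object of class `feature_matrix`: list with `x` (numeric
#'   matrix), `labels`, `center` and `in_mask_fraction` (fraction of cube
#'   voxels inside grid and mask).
#' @export
extract_cube_features <- function(cohort, center, cube_edge = 3L) {
  grid <- grid_shape(cohort)
  center <- as.integer(center)
  if (length(center) != 3L || any(center < 1L) || any(center > grid))
    stopf("extract_cube_features: 'center' is outside the grid")
  if (!cohort$mask[center[1], center[2], center[3]])
    stopf("extract_cube_features: 'center' is outside the mask")
  offs <- cube_offsets(cube_edge)
  pos <- sweep(offs, 2, center, `+`)
  in_grid <- pos[, 1] >= 1 & pos[, 1] <= grid[1] &
             pos[, 2] >= 1 & pos[, 2] <= grid[2] &
             pos[, 3] >= 1 & pos[, 3] <= grid[3]
  lin <- rep(0L, nrow(offs))
  lin[in_grid] <- pos[in_grid, 1] + grid[1] * (pos[in_grid, 2] - 1L) +
    grid[1] * grid[2] * (pos[in_grid, 3] - 1L)
  in_mask <- in_grid
  in_mask[in_grid] <- cohort$mask[lin[in_grid]]
  x <- matrix(0, n_subjects(cohort), nrow(offs))
  use <- in_mask
  x[, use] <- cohort_matrix(cohort)[, lin[use], drop = FALSE]
  structure(list(x = x, labels = cohort$subjects$group, center = center,
                 in_mask_fraction = mean(in_mask)),
            class = "feature_matrix")
}

#' Leave-one-out accuracy of the searchlight SVM at one voxel
#'
#' Runs the full nested cross-validation at a single voxel: each subject is
#' held out once; on the remaining subjects a grid search over `(C, gamma)` by
#' stratified `inner_folds`-fold CV selects the hyperparameters; the SVM is
#' refit on all training subjects with the winning pair and the held-out
#' subject is predicted.  The returned accuracy is the fraction of correct
#' held-out predictions — always an integer multiple of `1/n`.
#'
#' If every grid has a single point the inner search is skipped (the nested CV
#' is degenerate) and plain leave-one-out is performed.
#'
#' @param features A `feature_matrix` (from [extract_cube_features()]) or a
#'   numeric matrix.
#' @param config A [searchlight_config()].
#' @param labels `"A"`/`"B"` labels (taken from `features` when it is a
#'   `feature_matrix`).
#' @param voxel_index Integer identifying the voxel; combined with
#'   `config$seed` to seed inner-fold shuffling.
#' @param details Also return the per-fold training-set size, feature count
#'   and selected hyperparameters.
#' @return The accuracy, or (with `details = TRUE`) a list with `accuracy`,
#'   `n_correct`, `n` and a `folds` data frame.
#' @export
loo_accuracy_at_voxel <- function(features, config = searchlight_config(),
                                  labels = NULL, voxel_index = 0L,
                                  details = FALSE) {
  if (inherits(features, "feature_matrix")) {
    labels <- features$labels
    x <- features$x
  } else x <- as.matrix(features)
  y <- label_codes(labels)
  if (sum(y == 1L) < 2L || sum(y == -1L) < 2L)
    stopf("loo_accuracy_at_voxel: need at least 2 subjects per class")
  if (config$standardize) x <- standardize_columns(x)
  res <- .cpp_loo_accuracy(x, y, if (config$kernel == "linear") 0L else 1L,
                           config$c_grid, config$g_grid, config$inner_folds,
                           as.numeric(config$seed), as.numeric(voxel_index),
                           isTRUE(details))
  if (details) res else res$accuracy
}

standardize_columns <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(x, 2, mu), 2, sdv, `/`)
}

# Shared geometry of a searchlight run: per-voxel neighbour linear indices
# (0 where out of grid/mask), in-mask cube fraction, and the eligibility mask.
searchlight_geometry <- function(cohort, config) {
  grid <- grid_shape(cohort)
  nv <- prod(grid)
  offs <- cube_offsets(config$cube_edge)
  coords <- arrayInd(seq_len(nv), grid)
  nb <- matrix(0L, nv, nrow(offs))
  maskv <- as.vector(cohort$mask)
  for (o in seq_len(nrow(offs))) {
    ii <- coords[, 1] + offs[o, 1]
    jj <- coords[, 2] + offs[o, 2]
    kk <- coords[, 3] + offs[o, 3]
    ok <- ii >= 1 & ii <= grid[1] & jj >= 1 & jj <= grid[2] & kk >= 1 & kk <= grid[3]
    lin <- ii + grid[1] * (jj - 1L) + grid[1] * grid[2] * (kk - 1L)
    lin[!ok] <- 0L
    lin[ok][!maskv[lin[ok]]] <- 0L   # out-of-mask voxels imputed as background
    nb[, o] <- lin
  }
  frac <- rowMeans(nb > 0L)
  eligible <- maskv & frac >= config$min_in_mask_fraction
  list(nb = nb, frac = frac, eligible = eligible)
}

#' Whole-volume searchlight accuracy map
#'
#' The central fit of the package: at every eligible in-mask voxel, extracts
#' the cube-neighbourhood GM features of all subjects and computes the
#' leave-one-out SVM accuracy with nested hyperparameter selection (see
#' [loo_accuracy_at_voxel()]), producing a 3D accuracy map.  Voxels outside
#' the mask, or whose cube has less than `min_in_mask_fraction` of its voxels
#' in-mask, are `NaN`.
#'
#' Because each voxel's inner-fold shuffling is seeded from
#' `(config$seed, voxel index)`, the map does not depend on evaluation order,
#' and a re-run with the same configuration is bit-identical.
#'
#' @param cohort A [cohort_volumes()] object.
#' @param config A [searchlight_config()].
#' @param verbose Report progress every `progress_every` voxels.
#' @param progress_every Progress interval (voxels).
#' @return Object of class `searchlight_map`: list with `accuracy` (3D array),
#'   `n_subjects`, `n_evaluated`, `config`, `affine`, and `evaluated` (logical
#'   array of voxels that were classified).
#' @seealso [searchlight_map_reference()] for the plain-loop reference
#'   implementation, [pvalue_map()] for significance conversion.
#' @export
searchlight_map <- function(cohort, config = searchlight_config(),
                            verbose = FALSE, progress_every = 2000L) {
  if (!inherits(cohort, "cohort_volumes")) stopf("searchlight_map: 'cohort' must be cohort_volumes")
  if (!any(cohort$mask)) stopf("searchlight_map: empty mask")
  geo <- searchlight_geometry(cohort, config)
  grid <- grid_shape(cohort)
  y <- label_codes(cohort$subjects$group)
  if (sum(y == 1L) < 2L || sum(y == -1L) < 2L)
    stopf("searchlight_map: need at least 2 subjects per class")

  volmat <- cohort_matrix(cohort)
  vp <- cbind(0, volmat)       # column 1 = imputed background
  kern <- if (config$kernel == "linear") 0L else 1L
  acc <- rep(NaN, prod(grid))
  todo <- which(geo$eligible)
  for (m in seq_along(todo)) {
    v <- todo[m]
    x <- vp[, geo$nb[v, ] + 1L, drop = FALSE]
    if (config$standardize) x <- standardize_columns(x)
    acc[v] <- .cpp_loo_accuracy(x, y, kern, config$c_grid, config$g_grid,
                                config$inner_folds, as.numeric(config$seed),
                                as.numeric(v), FALSE)$accuracy
    if (verbose && m %% progress_every == 0L)
      message(sprintf("searchlight: %d/%d voxels", m, length(todo)))
  }
  structure(list(accuracy = array(acc, grid), n_subjects = length(y),
                 n_evaluated = length(todo), config = config,
                 affine = cohort$affine,
                 evaluated = array(seq_len(prod(grid)) %in% todo, grid)),
            class = "searchlight_map")
}

#' Reference (naive-loop) searchlight implementation
#'
#' An independently coded implementation of the searchlight used to validate
#' [searchlight_map()]: explicit loops over voxels, outer leave-one-out folds,
#' the hyperparameter grid and inner folds, with per-fit SVM training through
#' [svm_fit()].  It shares only the low-level quadratic-programming solver and
#' the deterministic fold-assignment primitive with the fast engine, so the
#' two paths cross-check the entire cross-validation and feature-extraction
#' machinery.  Both must produce bit-identical maps.
#'
#' @inheritParams searchlight_map
#' @return A `searchlight_map` object.
#' @export
searchlight_map_reference <- function(cohort, config = searchlight_config()) {
  grid <- grid_shape(cohort)
  labels <- cohort$subjects$group
  n <- n_subjects(cohort)
  r <- (config$cube_edge - 1L) / 2L
  pairs <- if (config$kernel == "linear") {
    data.frame(C = config$c_grid, gamma = NA_real_)
  } else {
    expand.grid(gamma = config$g_grid, C = config$c_grid)[, c("C", "gamma")]
  }
  # order ties: smallest C first, then smallest gamma
  pairs <- pairs[order(pairs$C, pairs$gamma), , drop = FALSE]

  acc <- array(NaN, grid)
  evaluated <- array(FALSE, grid)
  n_eval <- 0L
  for (k in seq_len(grid[3])) for (j in seq_len(grid[2])) for (i in seq_len(grid[1])) {
    if (!cohort$mask[i, j, k]) next
    # gather cube features by explicit loops, first axis fastest
    x <- matrix(0, n, config$cube_edge^3)
    col <- 0L
    n_in <- 0L
    for (dk in -r:r) {
      for (dj in -r:r) {
        for (di in -r:r) {
          col <- col + 1L
          ii <- i + di; jj <- j + dj; kk <- k + dk
          if (ii >= 1 && ii <= grid[1] && jj >= 1 && jj <= grid[2] &&
              kk >= 1 && kk <= grid[3] && cohort$mask[ii, jj, kk]) {
            x[, col] <- cohort$data[ii, jj, kk, ]
            n_in <- n_in + 1L
          }
        }
      }
    }
    if (n_in / col < config$min_in_mask_fraction) next
    if (config$standardize) x <- standardize_columns(x)
    vox <- i + grid[1] * (j - 1L) + grid[1] * grid[2] * (k - 1L)
    correct <- 0L
    for (t in seq_len(n)) {
      train <- setdiff(seq_len(n), t)
      xt <- x[train, , drop = FALSE]
      lt <- labels[train]
      if (nrow(pairs) > 1L) {
        fold <- stratified_fold_assignment(lt, config$inner_folds, config$seed,
                                           voxel_index = vox, outer_index = t)
        best <- NULL
        best_correct <- -1L
        for (p in seq_len(nrow(pairs))) {
          corr <- 0L
          for (f in seq_len(config$inner_folds)) {
            tr <- fold != f
            if (!any(!tr)) next
            fit <- svm_fit(xt[tr, , drop = FALSE], lt[tr], C = pairs$C[p],
                           kernel = config$kernel, gamma = pairs$gamma[p])
            pred <- predict(fit, xt[!tr, , drop = FALSE])
            corr <- corr + sum(pred == lt[!tr])
          }
          if (corr > best_correct) {
            best_correct <- corr
            best <- pairs[p, ]
          }
        }
      } else best <- pairs[1, ]
      fit <- svm_fit(xt, lt, C = best$C, kernel = config$kernel, gamma = best$gamma)
      pred <- predict(fit, x[t, , drop = FALSE])
      if (pred == labels[t]) correct <- correct + 1L
    }
    acc[i, j, k] <- correct / n
    evaluated[i, j, k] <- TRUE
    n_eval <- n_eval + 1L
  }
  structure(list(accuracy = acc, n_subjects = n, n_evaluated = n_eval,
                 config = config, affine = cohort$affine, evaluated = evaluated),
            class = "searchlight_map")
}

#' @export
print.searchlight_map <- function(x, ...) {
  a <- x$accuracy[x$evaluated]
  cat(sprintf("Searchlight accuracy map: %s grid, %d voxels evaluated, n = %d subjects\n",
              paste(dim(x$accuracy), collapse = "x"), x$n_evaluated, x$n_subjects))
  cat(sprintf("Kernel: %s; cube edge: %d; accuracy range %.3f-%.3f (mean %.3f)\n",
              x$config$kernel, x$config$cube_edge, min(a), max(a), mean(a)))
  invisible(x)
}

#' @export
summary.searchlight_map <- function(object, ...) {
  a <- object$accuracy[object$evaluated]
  out <- list(n_evaluated = object$n_evaluated, n_subjects = object$n_subjects,
              quantiles = stats::quantile(a, c(0, .25, .5, .75, 1)),
              mean = mean(a),
              peak_voxel = arrayInd(which.max(ifelse(object$evaluated, object$accuracy, -Inf)),
                                    dim(object$accuracy))[1, ])
  class(out) <- "summary.searchlight_map"
  out
}

#' @export
print.summary.searchlight_map <- function(x, ...) {
  cat(sprintf("Searchlight map: %d voxels, n = %d\n", x$n_evaluated, x$n_subjects))
  cat("Accuracy quantiles:\n")
  print(round(x$quantiles, 3))
  cat(sprintf("Mean accuracy: %.3f; peak at voxel (%s)\n", x$mean,
              paste(x$peak_voxel, collapse = ", ")))
  invisible(x)
}

#' @param x A `searchlight_map`.
#' @param slice Axial slice (third-axis index) to display; defaults to the
#'   slice containing the peak accuracy.
#' @param ... Passed to [graphics::image()].
#' @rdname searchlight_map
#' @export
plot.searchlight_map <- function(x, slice = NULL, ...) {
  if (is.null(slice)) {
    best <- arrayInd(which.max(ifelse(x$evaluated, x$accuracy, -Inf)), dim(x$accuracy))
    slice <- best[1, 3]
  }
  img <- x$accuracy[, , slice]
  graphics::image(img, zlim = c(0, 1), main = sprintf("LOO accuracy, slice %d", slice),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
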