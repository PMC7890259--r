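#' Exact binomial p-value of a classification accuracy
#'
#' Converts a cross-validated accuracy into the upper-tail probability of
#' observing at least as many correct predictions under a binomial null:
#' `p = P(X >= k)` with `X ~ Binomial(n, chance)` and `k = round(acc * n)`
#' (half-up rounding; accuracies are exact multiples of `1/n`, so rounding
#' only guards against floating-point error).  The tail is computed exactly
#' (no normal approximation).  For a fair-coin null at the distribution's
#' midpoint (`chance = 0.5`, `2k = n + 1`) the tail equals 1/2 by symmetry and
#' is returned analytically.
#'
#' @param acc Accuracy in `[0, 1]`; vectorized.  `NaN` propagates.
#' @param n Number of classified subjects (>= 1).
#' @param chance Null success probability in (0, 1); 0.5 corresponds to a
#'   balanced coin-flip null, `max(n_A, n_B)/n` to a majority-class prior.
#' @return Upper-tail p-value(s) in (0, 1].
#' @export
accuracy_to_pvalue <- function(acc, n, chance = 0.5) {
  if (!is_count(n)) stopf("accuracy_to_pvalue: 'n' must be a positive integer")
  if (!is.numeric(chance) || length(chance) != 1L || chance <= 0 || chance >= 1)
    stopf("accuracy_to_pvalue: 'chance' must be in (0, 1)")
  bad <- !is.nan(acc) & !is.na(acc) & (acc < 0 | acc > 1)
  if (any(bad)) stopf("accuracy_to_pvalue: accuracies must lie in [0, 1]")
  k <- floor(acc * n + 0.5)
  p <- pbinom(k - 1, n, chance, lower.tail = FALSE)
  if (chance == 0.5) p[!is.na(k) & 2 * k == n + 1] <- 0.5
  p[is.na(acc)] <- acc[is.na(acc)]  # keep NaN vs NA distinction
  p
}

#' Convert an accuracy map to a p-value map
#'
#' Applies [accuracy_to_pvalue()] voxel-wise; `NaN` (out-of-mask) voxels
#' propagate.
#'
#' @param x A [searchlight_map()] object or a 3D accuracy array.
#' @param n Subject count (taken from `x` when it is a `searchlight_map`).
#' @param chance Null success probability.
#' @return Object of class `pvalue_map`: list with `p` (3D array), `n`,
#'   `chance`, and (when available) `accuracy` and `affine` carried over from
#'   the input map.
#' @export
pvalue_map <- function(x, n = NULL, chance = 0.5) {
  if (inherits(x, "searchlight_map")) {
    acc <- x$accuracy
    n <- x$n_subjects
    affine <- x$affine
  } else {
    acc <- x
    affine <- attr(x, "affine")
    if (is.null(n)) stopf("pvalue_map: 'n' is required when 'x' is a plain array")
  }
  p <- array(accuracy_to_pvalue(as.vector(acc), n, chance), dim(acc))
  structure(list(p = p, n = n, chance = chance, accuracy = acc, affine = affine),
            class = "pvalue_map")
}

#' @export
print.pvalue_map <- function(x, ...) {
  v <- x$p[!is.na(x$p)]
  cat(sprintf("Binomial p-value map (n = %d, chance = %.3g): %d voxels, min p = %.3g\n",
              x$n, x$chance, length(v), if (length(v)) min(v) else NA))
  invisible(x)
}

#' Label connected components of a 3D binary mask
#'
#' @param mask Logical 3D array.
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (full) neighbourhood.
#' @return Integer 3D array of component labels (0 = background), numbered in
#'   column-major scan order of each component's first voxel.
#' @export
label_components <- function(mask, connectivity = 26L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stopf("label_components: 'connectivity' must be 6, 18 or 26")
  if (length(dim(mask)) != 3L) stopf("label_components: 'mask' must be a 3D array")
  m <- as.logical(mask)
  m[is.na(m)] <- FALSE
  .cpp_label_components(array(m, dim(mask)), as.integer(dim(mask)),
                        as.integer(connectivity))
}

# Core cluster tabulation shared by extract_clusters() and vbm_clusters():
# label a binary mask, filter components by size, locate peaks on peak_map.
clusters_from_mask <- function(binmask, min_cluster_size, connectivity,
                               peak_map = NULL, affine = NULL,
                               peak_by_abs = FALSE) {
  grid <- dim(binmask)
  labels <- label_components(binmask, connectivity)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes > min_cluster_size)

  rows <- lapply(keep, function(l) {
    vox <- which(labels == l)
    if (is.null(peak_map)) {
      peak <- min(vox)
      pval <- NA_real_
    } else {
      stat <- peak_map[vox]
      if (peak_by_abs) stat <- abs(stat)
      best <- max(stat)
      peak <- min(vox[stat == best])   # ties: smallest linear index
      pval <- peak_map[peak]
    }
    ijk <- arrayInd(peak, grid)[1, ]
    data.frame(size_voxels = sizes[l], peak_i = ijk[1], peak_j = ijk[2],
               peak_k = ijk[3], peak_value = pval, peak_linear = peak,
               orig_label = l)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(size_voxels = integer(), peak_i = integer(), peak_j = integer(),
               peak_k = integer(), peak_value = numeric(), peak_linear = integer(),
               orig_label = integer())
  # deterministic order: size descending, then peak linear index
  tab <- tab[order(-tab$size_voxels, tab$peak_linear), , drop = FALSE]
  tab$id <- seq_len(nrow(tab))

  relabel <- array(0L, grid)
  for (r in seq_len(nrow(tab))) relabel[labels == tab$orig_label[r]] <- r

  if (!is.null(affine) && nrow(tab)) {
    w <- voxel_to_world(as.matrix(tab[, c("peak_i", "peak_j", "peak_k")]), affine)
    tab$peak_x_mm <- w[, 1]; tab$peak_y_mm <- w[, 2]; tab$peak_z_mm <- w[, 3]
  } else {
    tab$peak_x_mm <- tab$peak_y_mm <- tab$peak_z_mm <- numeric(nrow(tab))
  }
  cols <- c("id", "size_voxels", "peak_i", "peak_j", "peak_k",
            "peak_x_mm", "peak_y_mm", "peak_z_mm", "peak_value")
  out <- tab[, cols, drop = FALSE]
  rownames(out) <- NULL
  structure(out, labels = relabel, n_suprathreshold = sum(binmask, na.rm = TRUE),
            class = c("cluster_table", "data.frame"))
}

#' Extract significant clusters from a p-value map
#'
#' Thresholds the map at `p < p_threshold` (strict), labels the suprathreshold
#' voxels into connected components, and returns components larger than
#' `min_cluster_size` voxels (strict, i.e. "more than" `min_cluster_size`),
#' sorted by size descending.  Each cluster's peak is the in-cluster voxel
#' maximizing `peak_map` (ties broken by smallest linear index).
#'
#' @param p_map A [pvalue_map()] object or 3D array of p-values (`NaN`/`NA`
#'   treated as out of mask).
#' @param p_threshold Cluster-forming threshold in (0, 1).
#' @param min_cluster_size Minimum cluster extent; clusters must exceed it.
#' @param connectivity 6, 18 or 26.
#' @param peak_map Statistic used to locate peaks (defaults to the accuracy
#'   map carried by a `pvalue_map`).
#' @param affine Optional 4x4 affine for peak world coordinates (defaults to
#'   the one carried by a `pvalue_map`).
#' @return A `cluster_table`: data frame with columns `id`, `size_voxels`,
#'   `peak_i/j/k` (1-based voxel), `peak_x/y/z_mm`, `peak_value`; the cluster
#'   label volume is attached as attribute `"labels"`.
#' @export
extract_clusters <- function(p_map, p_threshold = 0.001, min_cluster_size = 50L,
                             connectivity = 26L, peak_map = NULL, affine = NULL) {
  if (inherits(p_map, "pvalue_map")) {
    if (is.null(peak_map)) peak_map <- p_map$accuracy
    if (is.null(affine)) affine <- p_map$affine
    p <- p_map$p
  } else p <- p_map
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold >= 1)
    stopf("extract_clusters: 'p_threshold' must be in (0, 1)")
  supra <- !is.na(p) & p < p_threshold
  clusters_from_mask(supra, min_cluster_size, connectivity, peak_map, affine)
}

#' Binary mask of all voxels belonging to a cluster table
#'
#' @param clusters A `cluster_table` (or list of them, whose masks are
#'   OR-combined).
#' @return Logical 3D array.
#' @export
cluster_mask <- function(clusters) {
  if (inherits(clusters, "cluster_table")) return(attr(clusters, "labels") > 0)
  masks <- lapply(clusters, cluster_mask)
  Reduce(`|`, masks)
}

#' Write a cluster table as TSV
#'
#' @param clusters A `cluster_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  write.table(as.data.frame(clusters), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("%d cluster(s)", nrow(x)))
  if (nrow(x)) cat(sprintf(", sizes %s", paste(x$size_voxels, collapse = ", ")))
  cat("\n")
  if (nrow(x)) print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}
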