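#' Bundle subject volumes, mask, affine and demographics
#'
#' `cohort_volumes()` is the package's universal input container: a stack of
#' per-subject 3D gray-matter (GM) volume maps sharing one voxel grid and
#' world-space affine, a binary analysis mask, and a subject table with group
#' membership and covariates.  Every analysis stage (searchlight MVPA,
#' post hoc tests, VBM, ROC) consumes this representation.
#'
#' Group labels must be exactly the two levels `"A"` and `"B"`, each with at
#' least two members.  By convention group `B` is the case group (e.g. the
#' patient or exposure group) and group `A` the control group; all group
#' contrasts in the package are signed so that a positive statistic means
#' lower GM in group `B`.
#'
#' @param data Either a list of 3D numeric arrays (one per subject, all of the
#'   same dimensions) or a 4D array with subjects along the fourth axis.
#' @param mask Logical or 0/1 3D array on the same grid; voxels outside the
#'   mask are ignored by all analyses.
#' @param affine 4x4 voxel-to-world (mm) transform in the NIfTI convention.
#'   Voxel indices are R's 1-based indices; see [voxel_to_world()].
#' @param subjects `data.frame` with columns `id`, `group` (values `"A"`/`"B"`),
#'   `age` (years) and `gender` (`"M"`/`"F"`), one row per volume, in volume
#'   order.
#' @param check_nonnegative Require GM values inside the mask to be
#'   non-negative (the natural constraint for modulated GM maps).  Residual
#'   volumes produced by [regress_covariates()] switch this off.
#'
#' @return An object of class `cohort_volumes`: a list with elements `data`
#'   (4D array, subject last), `mask` (logical 3D array), `affine` and
#'   `subjects`.
#' @seealso [generate_cohort()], [load_cohort()]
#' @export
cohort_volumes <- function(data, mask, affine, subjects, check_nonnegative = TRUE) {
  if (is.list(data)) {
    dims <- lapply(data, dim)
    if (length(data) == 0L) stopf("'data' must contain at least one volume")
    ref <- dims[[1L]]
    for (i in seq_along(dims)) {
      if (length(dims[[i]]) != 3L || !identical(dims[[i]], ref))
        stopf("volume %d has grid %s; expected %s", i,
              paste(dims[[i]], collapse = "x"), paste(ref, collapse = "x"))
    }
    data <- array(unlist(data, use.names = FALSE), dim = c(ref, length(data)))
  }
  if (!is.array(data) || length(dim(data)) != 4L)
    stopf("'data' must be a list of 3D arrays or a 4D array")
  grid <- dim(data)[1:3]
  n <- dim(data)[4L]

  if (is.null(dim(mask)) || !identical(as.integer(dim(mask)), as.integer(grid)))
    stopf("mask grid (%s) does not match volume grid (%s)",
          paste(dim(mask), collapse = "x"), paste(grid, collapse = "x"))
  mask <- array(as.logical(mask), dim = grid)
  if (anyNA(mask)) stopf("mask contains missing values")
  if (!any(mask)) stopf("mask is empty")

  if (!is.matrix(affine) || !identical(dim(affine), c(4L, 4L)) || !all(is.finite(affine)))
    stopf("'affine' must be a finite 4x4 matrix")

  if (!is.data.frame(subjects))
    stopf("'subjects' must be a data.frame")
  req <- c("id", "group", "age", "gender")
  missing_cols <- setdiff(req, names(subjects))
  if (length(missing_cols))
    stopf("subject table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(subjects) != n)
    stopf("subject table has %d rows but there are %d volumes", nrow(subjects), n)
  grp <- as.character(subjects$group)
  bad <- setdiff(unique(grp), c("A", "B"))
  if (length(bad))
    stopf("unknown group level(s): %s (groups must be 'A' and 'B')",
          paste(bad, collapse = ", "))
  if (sum(grp == "A") < 2L || sum(grp == "B") < 2L)
    stopf("each group needs at least 2 members (found A=%d, B=%d)",
          sum(grp == "A"), sum(grp == "B"))
  if (!is.numeric(subjects$age) || anyNA(subjects$age))
    stopf("'age' must be numeric and complete")
  gen <- as.character(subjects$gender)
  if (!all(gen %in% c("M", "F")))
    stopf("'gender' must be 'M' or 'F'")
  subjects$group <- grp
  subjects$gender <- gen

  if (check_nonnegative) {
    vals <- matrix(data, prod(grid), n)[as.vector(mask), , drop = FALSE]
    if (any(vals < 0, na.rm = TRUE))
      stopf("GM values inside the mask must be non-negative")
  }

  structure(list(data = data, mask = mask, affine = affine, subjects = subjects),
            class = "cohort_volumes")
}

#' @export
print.cohort_volumes <- function(x, ...) {
  grid <- dim(x$data)[1:3]
  n <- dim(x$data)[4L]
  grp <- table(x$subjects$group)
  cat(sprintf("Cohort of %d subjects (A=%d, B=%d) on a %s grid, %d in-mask voxels\n",
              n, grp[["A"]], grp[["B"]], paste(grid, collapse = "x"), sum(x$mask)))
  vx <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  cat(sprintf("Voxel size: %s mm; mean in-mask GM value: %.4g\n",
              paste(signif(vx, 4), collapse = " x "),
              mean(cohort_matrix(x)[, as.vector(x$mask), drop = FALSE])))
  invisible(x)
}

#' Subjects-by-voxels data matrix of a cohort
#'
#' @param cohort A [cohort_volumes()] object.
#' @return Numeric matrix with one row per subject and one column per voxel
#'   (column-major voxel order).
#' @export
cohort_matrix <- function(cohort) {
  d <- dim(cohort$data)
  t(matrix(cohort$data, prod(d[1:3]), d[4L]))
}

n_subjects <- function(cohort) dim(cohort$data)[4L]

grid_shape <- function(cohort) dim(cohort$data)[1:3]
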