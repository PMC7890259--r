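#' Load a cohort from NIfTI volumes and a subject table
#'
#' Reads one NIfTI GM map per subject plus a binary mask, checks that every
#' volume shares the mask's grid and affine (within `tol` mm), and pairs them
#' with a CSV subject table (columns `id`, `group`, `age`, `gender`; rows in
#' volume order).
#'
#' @param volume_paths Character vector of NIfTI file paths, one per subject.
#' @param mask_path Path to the binary mask NIfTI.
#' @param subjects_path Path to the subject CSV.
#' @param tol Affine agreement tolerance in mm.
#' @return A [cohort_volumes()] object.
#' @export
load_cohort <- function(volume_paths, mask_path, subjects_path, tol = 1e-4) {
  mask_img <- RNifti::readNifti(mask_path)
  affine <- unclass(RNifti::xform(mask_img))
  attributes(affine) <- list(dim = dim(affine))
  grid <- dim(mask_img)
  if (length(grid) != 3L) stopf("mask '%s' is not a 3D volume", mask_path)

  vols <- vector("list", length(volume_paths))
  for (i in seq_along(volume_paths)) {
    img <- RNifti::readNifti(volume_paths[[i]])
    if (!identical(as.integer(dim(img)), as.integer(grid)))
      stopf("volume '%s' has grid %s but the mask grid is %s", volume_paths[[i]],
            paste(dim(img), collapse = "x"), paste(grid, collapse = "x"))
    a <- unclass(RNifti::xform(img))
    if (max(abs(a - affine)) > tol)
      stopf("volume '%s' has an affine differing from the mask by %.3g mm (tol %.3g)",
            volume_paths[[i]], max(abs(a - affine)), tol)
    vols[[i]] <- array(as.numeric(img), dim = grid)
  }

  subjects <- read.csv(subjects_path, stringsAsFactors = FALSE)
  if (nrow(subjects) != length(volume_paths))
    stopf("subject table '%s' has %d rows but %d volumes were given",
          subjects_path, nrow(subjects), length(volume_paths))
  cohort_volumes(vols, array(as.numeric(mask_img) != 0, grid), affine, subjects)
}

#' Save a 3D statistical map as NIfTI
#'
#' Writes `map` in float32 with the given affine (sform and qform, code 2).
#' `NaN`/`NA` values (the package's out-of-mask marker) are preserved.
#'
#' @param map 3D numeric array.
#' @param affine 4x4 voxel-to-world transform.
#' @param path Output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_map <- function(map, affine, path) {
  if (length(dim(map)) != 3L) stopf("save_map: 'map' must be a 3D array")
  img <- RNifti::asNifti(map)
  RNifti::`sform<-`(img, structure(affine, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Load a statistical map saved by [save_map()]
#'
#' @param path NIfTI file path.
#' @return 3D array with the affine attached as attribute `"affine"`.
#' @export
load_map <- function(path) {
  img <- RNifti::readNifti(path)
  a <- unclass(RNifti::xform(img))
  attributes(a) <- list(dim = dim(a))
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "affine") <- a
  out
}

#' Convert between voxel and world (mm) coordinates
#'
#' Voxel indices are R's 1-based indices; the affine follows the NIfTI
#' convention (it maps 0-based indices to world mm), so
#' `world = affine %*% c(ijk - 1, 1)`.
#'
#' @param ijk Voxel coordinates: length-3 vector or n-by-3 matrix.
#' @param affine 4x4 voxel-to-world transform.
#' @return Length-3 vector or n-by-3 matrix of world coordinates.
#' @export
voxel_to_world <- function(ijk, affine) {
  v <- if (is.matrix(ijk)) t(ijk) else matrix(ijk, 3)
  w <- affine %*% rbind(v - 1, 1)
  if (is.matrix(ijk)) t(w[1:3, , drop = FALSE]) else w[1:3, 1]
}

#' @param xyz World coordinates: length-3 vector or n-by-3 matrix.
#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(xyz, affine) {
  w <- if (is.matrix(xyz)) t(xyz) else matrix(xyz, 3)
  v <- solve(affine) %*% rbind(w, 1)
  out <- v[1:3, , drop = FALSE] + 1
  if (is.matrix(xyz)) t(out) else out[, 1]
}

#' Write a cohort to disk
#'
#' Writes one NIfTI volume per subject (`<prefix>-001.nii.gz`, ...), the mask
#' (`mask.nii.gz`) and the subject table (`subjects.csv`) into `dir`.
#'
#' @param cohort A [cohort_volumes()] object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix for subject volumes.
#' @param gzip Compress volumes (`.nii.gz`) or not (`.nii`).
#' @return A list with `volumes`, `mask` and `subjects` paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "sub", gzip = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  n <- n_subjects(cohort)
  vpaths <- file.path(dir, sprintf("%s-%03d%s", prefix, seq_len(n), ext))
  for (i in seq_len(n))
    save_map(cohort$data[, , , i], cohort$affine, vpaths[i])
  mpath <- file.path(dir, paste0("mask", ext))
  save_map(array(as.numeric(cohort$mask), dim(cohort$mask)), cohort$affine, mpath)
  spath <- file.path(dir, "subjects.csv")
  utils::write.csv(cohort$subjects, spath, row.names = FALSE)
  invisible(list(volumes = vpaths, mask = mpath, subjects = spath))
}
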