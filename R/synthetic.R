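#' Define a localized group-effect region
#'
#' Describes a spherical or cuboid region of the voxel grid in which the mean
#' GM value of group `B` (the case group) differs from group `A` by
#' `delta`.  Negative `delta` emulates regional GM volume loss in the case
#' group — the typical direction in structural case-control studies — and
#' positive `delta` a regional increase.
#'
#' @param center Voxel coordinates (3 integers, 1-based) of the region center.
#' @param delta Signed mean GM difference (group B minus group A), in GM-value
#'   units, applied before smoothing.
#' @param radius Radius in voxels for `shape = "sphere"` (voxels within
#'   Euclidean distance `radius` of the center belong to the region).
#' @param extents Full widths in voxels per axis (3 odd integers) for
#'   `shape = "cube"`.
#' @param shape `"sphere"` or `"cube"`.
#' @return An object of class `effect_region`.
#' @export
effect_region <- function(center, delta, radius = NULL, extents = NULL,
                          shape = c("sphere", "cube")) {
  shape <- match.arg(shape)
  if (length(center) != 3L || any(center != round(center)))
    stopf("effect_region: 'center' must be 3 integer voxel indices")
  if (shape == "sphere") {
    if (!is_count(radius, min = 0L)) stopf("effect_region: 'radius' must be a non-negative integer")
  } else {
    if (is.null(extents) || length(extents) != 3L || any(extents < 1) ||
        any(extents != round(extents)) || any(extents %% 2 == 0))
      stopf("effect_region: 'extents' must be 3 odd positive integers")
  }
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta))
    stopf("effect_region: 'delta' must be a finite number")
  structure(list(center = as.integer(center), delta = delta,
                 radius = if (shape == "sphere") as.integer(radius),
                 extents = if (shape == "cube") as.integer(extents),
                 shape = shape),
            class = "effect_region")
}

region_mask <- function(region, grid) {
  ax <- lapply(1:3, function(a) seq_len(grid[a]) - region$center[a])
  m <- array(FALSE, grid)
  if (region$shape == "sphere") {
    d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
    m[] <- d2 <= region$radius^2
  } else {
    half <- (region$extents - 1L) / 2L
    ok1 <- abs(ax[[1]]) <= half[1]
    ok2 <- abs(ax[[2]]) <= half[2]
    ok3 <- abs(ax[[3]]) <= half[3]
    m[] <- outer(outer(ok1, ok2, `&`), ok3, `&`)
  }
  m
}

region_inside_grid <- function(region, grid) {
  if (region$shape == "sphere") {
    lo <- region$center - region$radius
    hi <- region$center + region$radius
  } else {
    half <- (region$extents - 1L) / 2L
    lo <- region$center - half
    hi <- region$center + half
  }
  all(lo >= 1L) && all(hi <= grid)
}

#' Configure the synthetic-cohort generator
#'
#' The generator emulates the statistical structure of preprocessed
#' (segmented, modulated, smoothed) gray-matter maps from a two-group
#' structural MRI study: a shared smooth anatomical template, localized
#' group-mean differences, optional linear covariate loadings, and
#' between-subject Gaussian noise, all blurred by a Gaussian kernel as real
#' GM maps are in the final preprocessing step.
#'
#' Defaults mirror a 37-case / 28-control cohort: 1.5 mm isotropic voxels,
#' 8 mm FWHM smoothing, case ages 47.2 +/- 7.2 years with 29/37 male, control
#' ages 43 +/- 9.6 years with 20/28 male.  `noise_sd = 0.05` puts
#' between-subject variability at roughly 10% of the template's dynamic range
#' (template values span 0.2-0.8 in arbitrary GM units).
#'
#' @param grid_shape Voxel counts per axis (3 integers, each >= 8).
#' @param voxel_size_mm Isotropic voxel spacing in mm.
#' @param n_group_a,n_group_b Subjects in the control (A) and case (B) group.
#' @param effect_regions List of [effect_region()] objects; the `delta` of
#'   each is added to group-B volumes inside the region, before smoothing.
#' @param noise_sd Between-subject Gaussian noise SD (GM-value units), > 0.
#' @param smooth_fwhm_mm Gaussian smoothing kernel FWHM in mm (>= 0; 0 skips
#'   smoothing).
#' @param covariate_model Optional list with any of: `age_region`
#'   ([effect_region()]), `age_slope` (GM units per SD of age), and
#'   `gender_region`, `gender_delta` (GM offset for males).  `NULL` (default)
#'   means no covariate loadings.
#' @param age_mean_a,age_sd_a,age_mean_b,age_sd_b Group age distributions
#'   (years).
#' @param male_prop_a,male_prop_b Probability that a subject is male, per
#'   group.
#' @param seed Integer RNG seed; identical configurations generate
#'   bit-identical cohorts.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(grid_shape = c(32L, 32L, 32L), voxel_size_mm = 1.5,
                         n_group_a = 28L, n_group_b = 37L,
                         effect_regions = list(), noise_sd = 0.05,
                         smooth_fwhm_mm = 8, covariate_model = NULL,
                         age_mean_a = 43, age_sd_a = 9.62,
                         age_mean_b = 47.18, age_sd_b = 7.22,
                         male_prop_a = 20 / 28, male_prop_b = 29 / 37,
                         seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 8) || any(grid_shape != round(grid_shape)))
    stopf("synth_config: 'grid_shape' must be 3 integers >= 8")
  if (!is.numeric(voxel_size_mm) || voxel_size_mm <= 0)
    stopf("synth_config: 'voxel_size_mm' must be positive")
  if (!is_count(n_group_a, 2L)) stopf("synth_config: 'n_group_a' must be an integer >= 2")
  if (!is_count(n_group_b, 2L)) stopf("synth_config: 'n_group_b' must be an integer >= 2")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stopf("synth_config: 'noise_sd' must be > 0")
  if (!is.numeric(smooth_fwhm_mm) || smooth_fwhm_mm < 0)
    stopf("synth_config: 'smooth_fwhm_mm' must be >= 0")
  if (!is.list(effect_regions))
    stopf("synth_config: 'effect_regions' must be a list of effect_region objects")
  grid <- as.integer(round(grid_shape))
  for (i in seq_along(effect_regions)) {
    r <- effect_regions[[i]]
    if (!inherits(r, "effect_region"))
      stopf("synth_config: 'effect_regions[[%d]]' is not an effect_region", i)
    if (!region_inside_grid(r, grid))
      stopf("synth_config: 'effect_regions[[%d]]' extends outside the grid", i)
  }
  if (!is.null(covariate_model)) {
    if (!is.list(covariate_model))
      stopf("synth_config: 'covariate_model' must be a list or NULL")
    for (nm in c("age_region", "gender_region")) {
      r <- covariate_model[[nm]]
      if (!is.null(r) && (!inherits(r, "effect_region") || !region_inside_grid(r, grid)))
        stopf("synth_config: 'covariate_model$%s' must be an effect_region inside the grid", nm)
    }
  }
  for (p in c("male_prop_a", "male_prop_b")) {
    v <- get(p)
    if (!is.numeric(v) || v < 0 || v > 1) stopf("synth_config: '%s' must be in [0, 1]", p)
  }
  structure(list(grid_shape = grid, voxel_size_mm = voxel_size_mm,
                 n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
                 effect_regions = effect_regions, noise_sd = noise_sd,
                 smooth_fwhm_mm = smooth_fwhm_mm, covariate_model = covariate_model,
                 age_mean_a = age_mean_a, age_sd_a = age_sd_a,
                 age_mean_b = age_mean_b, age_sd_b = age_sd_b,
                 male_prop_a = male_prop_a, male_prop_b = male_prop_b,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Gaussian-smooth a 3D volume
#'
#' Separable Gaussian convolution with `sigma = fwhm / (2 * sqrt(2 * log(2)))`
#' per axis, in voxel units.  The kernel is truncated at four standard
#' deviations and renormalized at the grid boundary (each output voxel is a
#' unit-weight average of its in-grid neighbourhood), so interior mass is
#' preserved but edge voxels are not guaranteed mass-preserving.
#'
#' @param volume 3D numeric array.
#' @param fwhm_mm Kernel full width at half maximum, mm (>= 0; 0 returns the
#'   input unchanged).
#' @param voxel_size_mm Isotropic voxel spacing, mm.
#' @return Smoothed 3D array of the same dimensions.
#' @export
smooth_volume <- function(volume, fwhm_mm, voxel_size_mm = 1) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0)
    stopf("smooth_volume: 'fwhm_mm' must be a single non-negative number")
  if (length(dim(volume)) != 3L) stopf("smooth_volume: 'volume' must be a 3D array")
  if (fwhm_mm == 0) return(volume)
  sigma <- fwhm_mm / voxel_size_mm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-(0:r)^2 / (2 * sigma^2))

  smat <- function(n) {
    S <- matrix(0, n, n)
    for (off in -r:r) {
      idx <- seq_len(n)
      keep <- idx + off >= 1L & idx + off <= n
      S[cbind(idx[keep], (idx + off)[keep])] <- w[abs(off) + 1L]
    }
    S / rowSums(S)
  }
  d <- dim(volume)
  v <- array(smat(d[1]) %*% matrix(volume, d[1]), d)
  p <- aperm(v, c(2, 1, 3))
  p <- array(smat(d[2]) %*% matrix(p, d[2]), dim(p))
  v <- aperm(p, c(2, 1, 3))
  p <- aperm(v, c(3, 1, 2))
  p <- array(smat(d[3]) %*% matrix(p, d[3]), dim(p))
  aperm(p, c(2, 3, 1))
}

synth_template <- function(config) {
  grid <- config$grid_shape
  z <- with_local_seed(stage_seed(config$seed, "template"),
                       array(rnorm(prod(grid)), grid))
  # low-frequency positive random field: heavy blur, then min-max rescale
  z <- smooth_volume(z, fwhm_mm = 6 * config$voxel_size_mm, config$voxel_size_mm)
  rng <- range(z)
  0.2 + 0.6 * (z - rng[1]) / (rng[2] - rng[1])
}

synth_affine <- function(config) {
  v <- config$voxel_size_mm
  a <- diag(c(v, v, v, 1))
  a[1:3, 4] <- -v * (config$grid_shape - 1) / 2
  a
}

#' Generate a synthetic two-group cohort of GM-like volumes
#'
#' Each subject volume is built as
#' `template + group effect (group B only) + covariate loadings + iid noise`,
#' then Gaussian-smoothed at `smooth_fwhm_mm` and floored at zero.  The shared
#' template is a smooth positive random field (values 0.2-0.8); the analysis
#' mask is `template > 0.1`.  Effects are injected before smoothing so that
#' observed group differences are spatially blurred exactly as effects in real
#' modulated GM maps are.
#'
#' The generator is fully deterministic given `config$seed`, and it restores
#' the caller's RNG state.
#'
#' @param config A [synth_config()] object.
#' @return A [cohort_volumes()] object.
#' @examples
#' cfg <- synth_config(grid_shape = c(10, 10, 10), n_group_a = 4, n_group_b = 4,
#'                     smooth_fwhm_mm = 3, seed = 7)
#' cohort <- generate_cohort(cfg)
#' cohort
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config"))
    stopf("generate_cohort: 'config' must be a synth_config object")
  grid <- config$grid_shape
  template <- synth_template(config)
  mask <- template > 0.1
  na <- config$n_group_a
  nb <- config$n_group_b
  n <- na + nb

  effect <- array(0, grid)
  for (r in config$effect_regions)
    effect[region_mask(r, grid)] <- effect[region_mask(r, grid)] + r$delta

  cm <- config$covariate_model
  age_mask <- if (!is.null(cm$age_region)) region_mask(cm$age_region, grid)
  gender_mask <- if (!is.null(cm$gender_region)) region_mask(cm$gender_region, grid)

  out <- with_local_seed(config$seed, {
    age <- c(rnorm(na, config$age_mean_a, config$age_sd_a),
             rnorm(nb, config$age_mean_b, config$age_sd_b))
    gender <- ifelse(c(rbinom(na, 1, config$male_prop_a),
                       rbinom(nb, 1, config$male_prop_b)) == 1, "M", "F")
    age_z <- (age - mean(age)) / sd(age)
    vols <- array(0, dim = c(grid, n))
    for (i in seq_len(n)) {
      v <- template
      if (i > na) v <- v + effect
      if (!is.null(age_mask)) v[age_mask] <- v[age_mask] + cm$age_slope * age_z[i]
      if (!is.null(gender_mask) && gender[i] == "M")
        v[gender_mask] <- v[gender_mask] + cm$gender_delta
      v <- v + array(rnorm(prod(grid), 0, config$noise_sd), grid)
      v <- smooth_volume(v, config$smooth_fwhm_mm, config$voxel_size_mm)
      vols[, , , i] <- pmax(v, 0)
    }
    list(vols = vols, age = age, gender = gender)
  })

  subjects <- data.frame(
    id = sprintf("S%03d", seq_len(n)),
    group = rep(c("A", "B"), c(na, nb)),
    age = out$age,
    gender = out$gender,
    stringsAsFactors = FALSE
  )
  cohort_volumes(out$vols, mask, synth_affine(config), subjects)
}

#' Ground-truth effect mask of a synthetic configuration
#'
#' Marks exactly the voxels lying inside any effect region whose `delta` is
#' nonzero — the reference against which effect-recovery of the analysis
#' pipeline is scored.
#'
#' @param config A [synth_config()] object.
#' @return Logical 3D array.
#' @export
true_effect_mask <- function(config) {
  if (!inherits(config, "synth_config"))
    stopf("true_effect_mask: 'config' must be a synth_config object")
  m <- array(FALSE, config$grid_shape)
  for (r in config$effect_regions)
    if (r$delta != 0) m <- m | region_mask(r, config$grid_shape)
  m
}

#' Dilate a binary mask by a Chebyshev radius
#'
#' Cubic structuring-element dilation: a voxel is set if any voxel within
#' `radius` steps along each axis (26-neighbourhood metric) is set.  Used to
#' widen a ground-truth effect mask by the searchlight cube radius plus the
#' smoothing support before overlap scoring.
#'
#' @param mask Logical 3D array.
#' @param radius Non-negative integer.
#' @return Logical 3D array.
#' @export
dilate_mask <- function(mask, radius) {
  if (!is_count(radius, 0L)) stopf("dilate_mask: 'radius' must be a non-negative integer")
  d <- dim(mask)
  out <- mask
  if (radius == 0L) return(out)
  for (a in -radius:radius) for (b in -radius:radius) for (c in -radius:radius) {
    if (a == 0 && b == 0 && c == 0) next
    src <- list(seq_len(d[1]) - a, seq_len(d[2]) - b, seq_len(d[3]) - c)
    ok <- lapply(1:3, function(i) src[[i]] >= 1 & src[[i]] <= d[i])
    out[ok[[1]], ok[[2]], ok[[3]]] <-
      out[ok[[1]], ok[[2]], ok[[3]]] |
      mask[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  }
  out
}

#' Dice overlap coefficient of two binary masks
#'
#' @param a,b Logical arrays of identical dimensions.
#' @return `2|a & b| / (|a| + |b|)`; `NaN` if both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stopf("dice_coefficient: masks have different grids")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NaN)
  2 * sum(a & b) / denom
}
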