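---
title: "Searchlight MVPA of gray-matter maps: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searchlight MVPA of gray-matter maps: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette describes the statistical machinery of the package: what each
stage assumes, the tunable parameters and their defaults, the numerical
choices made where the design was genuinely open, and what validation on
synthetic cohorts does and does not establish about real data.

## The analysis problem

The package analyzes cohorts of preprocessed structural gray-matter (GM)
volume maps — segmented, modulated, smoothed maps in which each voxel value
is a local tissue-volume quantity — for a two-group case-control design.
Group `B` is, by convention, the case group; every signed statistic in the
package is oriented so that *positive means lower GM in group `B`*.

Two complementary detection strategies are implemented:

* **Searchlight multivoxel pattern analysis (MVPA)**: at every voxel a
  support vector machine (SVM) is trained on the joint pattern of the
  surrounding 3×3×3 cube (27 features) and scored by leave-one-out (LOO)
  cross-validation, producing a whole-volume *accuracy map*. Multivariate
  patterns that no single voxel shows can be detected this way.
* **Voxel-based morphometry (VBM)**: the classical univariate voxel-wise
  general linear model with nuisance covariates, thresholded into clusters.

A post hoc stage tests GM differences inside MVPA-detected clusters with
covariate adjustment and permutation-based family-wise-error (FWE) control,
and an ROC stage benchmarks how well region-mean GM features discriminate
the groups under cross-validation.

## The searchlight classifier

At voxel $v$ the feature matrix has one row per subject and one column per
cube voxel (edge length `cube_edge`, default 3; columns in column-major scan
order, first axis fastest). The outer loop is leave-one-out: each subject is
held out once, the SVM is trained on the remaining $n-1$, and the held-out
subject is predicted; the voxel's accuracy is the fraction of correct
held-out predictions, always an exact multiple of $1/n$. Hyperparameters are
selected *inside* each outer training set by stratified `inner_folds`-fold
cross-validation (default 5) over a log-2 grid, so no test information leaks
into model selection.

Open design points and how they were fixed:

* **Kernel.** The default is a linear SVM with the regularization grid
  $C \in \{2^{-5}, 2^{-3}, \dots, 2^9\}$. An RBF mode additionally tunes
  $\gamma \in \{2^{-9}, \dots, 2^3\}$; both are first-class because the two
  descriptions of this family of analyses (linear SVM vs. a tuned RBF
  $\gamma$) are not mutually consistent, and we did not guess the intent.
* **Tie-breaking.** Inner-CV ties are resolved deterministically: highest
  inner accuracy, then smallest $C$, then smallest $\gamma$.
* **Edges.** Cube voxels outside the grid or mask are imputed as 0
  (background GM). A center voxel is skipped (`NaN`) when less than
  `min_in_mask_fraction` (default 0.5) of its cube lies in-mask.
* **Features are used raw** (no standardization) by default, matching the
  convention of feeding modulated GM values directly to the classifier; a
  `standardize` switch exists.
* **No covariate regression before classification** — the searchlight
  operates on the unadjusted maps; covariates enter only in the post hoc and
  VBM stages.

### Determinism and the solver

The quadratic program of the C-SVM is solved by a package-internal SMO
solver (maximal-violating-pair working-set selection, stopping tolerance
$10^{-3}$, the convention of LIBSVM). The solver is validated in the test
suite against `e1071`/libsvm: on clear-margin problems the two optimizers
agree in every prediction and to solver tolerance in decision values. A
dedicated plain-loop reference implementation of the whole searchlight
(`searchlight_map_reference()`) — independent loops for feature extraction,
outer folds, grid search and inner folds — must produce *bit-identical*
accuracy maps to the fast engine.

All inner-fold shuffling derives from `(seed, voxel index, outer fold)`
through a counter-based generator, so maps do not depend on evaluation order
and re-runs are exactly reproducible. R's global RNG is never consumed.

### A caution on the LOO null distribution

On null data with (near-)balanced groups, LOO accuracy is *pessimistic*, not
centered at chance: holding out a subject tilts the training majority toward
the other class, and an SVM that cannot find signal predicts that majority.
Null-cohort accuracy maps therefore concentrate *below* 0.5 rather than at
0.5. Two consequences are worth knowing:

* the binomial conversion below is **conservative** under the null (true
  false-positive rates are lower than nominal);
* mean null accuracy is not a chance-level estimator, so the package's null
  tests assert "not above chance", not equality with chance.

## From accuracy to significance

Accuracies are converted to upper-tail p-values under a binomial null:
$p = P(X \ge k)$, $X \sim \mathrm{Binomial}(n, \theta)$, $k =$ the number of
correct predictions. The tail is computed exactly (no normal approximation).
The chance level $\theta$ defaults to 0.5; an option uses the majority-class
prior (e.g. $37/65 \approx 0.569$) instead. One numerical special case: for
$\theta = 1/2$ at the distribution's midpoint ($2k = n+1$) the tail equals
exactly $1/2$ by symmetry and is returned analytically, because naive
summation leaves an avoidable $\sim 2\times10^{-16}$ residual. The
conversion is verified against exact rational enumeration for all
$k, n \le 20$.

Cluster inference thresholds the p-map at $p < 0.001$ (strict) and labels
suprathreshold voxels into connected components — default connectivity 26,
i.e. full 3D adjacency, since "connected" is otherwise underspecified —
keeping components of *more than* `min_cluster_size` voxels (default 50,
read strictly). Peaks are the in-cluster maximum of the accuracy map, ties
broken by smallest linear index, so tables are fully deterministic.

## Post hoc inference with permutation FWE

Within the MVPA-detected clusters, GM differences are tested voxel-wise by
two-sample pooled-variance t-tests after removing age and gender by voxel-wise
least squares (`regress_covariates()`; the nuisance model pools groups and
deliberately excludes the group factor, so group signal survives; the
operation is idempotent and residuals keep the voxel grand mean).

Cluster-level FWE control is *permutation-based*: clusters are formed on
$|t| > t_{crit}$ at the two-tailed cluster-forming threshold (default
$p < 0.001$), and the null distribution of the maximum cluster extent is
built by relabeling group assignments `n_permutations` times (labels are
permuted on the covariate-adjusted data; nuisance effects are not
re-estimated per permutation — a Freedman–Lane-style simplification, stated
openly). The corrected p-value of an observed cluster of size $s$ is
$(1 + \#\{\text{null max} \ge s\})/(B+1)$, floored at $1/(B+1)$. This is a
deliberate design decision: the classical alternative is parametric
random-field-theory cluster FWE, which needs smoothness estimation and
external machinery; label permutation is distribution-free, self-contained
and directly testable. Calibration is checked empirically: on null cohorts
the fraction of runs with any surviving cluster stays inside the binomial
envelope of the nominal 5%.

## Whole-brain VBM

`wholebrain_tmap()` fits `GM ~ intercept + group + age + gender` per voxel
and reports the group-contrast t statistic (sign convention as above,
residual dof $n - p$). With no covariates it reduces exactly to the pooled
two-sample t map — a cross-check in the test suite. Signed cluster tables
are formed separately from $t > t_{crit}$ (case group lower) and
$t < -t_{crit}$, with the same size filter (> 50 voxels) and peaks by $|t|$.

## ROC benchmark

For a set of detected regions, the mean GM value per region and subject is
the feature vector. A stratified 5-fold cross-validation trains an SVM per
fold (nested 3-fold grid selection) and collects out-of-fold probabilities
of being a case, one per subject. Probabilities come from Platt sigmoid
scaling fitted by deterministic Newton iteration to *inner-CV decision
values of the training fold only* — the classical approach, re-implemented
here because libsvm's built-in calibration draws on a process-global RNG and
is not reproducible across calls. AUC is computed by the rank (Mann–Whitney)
method with ties counted half, identical to the trapezoidal area, and
verified against brute-force pairwise concordance. Operating-point metrics
(sensitivity, specificity, PPV, NPV) are reported at a fixed 0.5 threshold
by default; a Youden-J rule is available but flagged as data-dependent.

## The synthetic cohort generator

Real modulated GM maps from case-control MRI studies are rarely shareable,
so validation runs on synthetic cohorts that emulate their statistical
structure:

* a shared anatomical **template**: a smooth positive random field (white
  noise heavily blurred, min-max rescaled to $[0.2, 0.8]$ arbitrary GM
  units); the analysis mask is `template > 0.1`. A random field avoids
  shipping any real template; GM amplitudes are in arbitrary units because
  the dynamic range of real modulated maps is protocol-dependent.
* **group effects**: spherical or cuboid regions where group B's mean is
  shifted by `effect_delta` (negative = GM loss in cases, the typical
  direction), applied *before* smoothing so observed effects are spatially
  blurred exactly as real VBM effects are;
* **covariate loadings**: optionally, GM varies linearly with standardized
  age over a region (and/or by gender), enabling the covariate-adjustment
  tests;
* **noise**: i.i.d. between-subject Gaussian noise (`noise_sd`, default
  0.05 ≈ 10% of the template range), then Gaussian smoothing at
  `smooth_fwhm_mm` (default 8 mm at 1.5 mm voxels, the conventional
  preprocessing kernel), then a floor at 0 (GM volumes are non-negative).

Demographics default to a 37-case/28-control cohort: case ages
$47.2 \pm 7.2$ years with 29/37 male, control ages $43 \pm 9.6$ with 20/28
male. Smoothing uses a truncated (4σ) renormalized kernel; interior mass is
preserved (verified to $10^{-6}$ for spikes at least twice the kernel radius
from the boundary) but edge voxels are *not* mass-preserving — the boundary
is renormalized, a documented contract.

What the generator does **not** emulate: segmentation and registration
artifacts, scanner noise spectra, nonlinear-warp (DARTEL-like) distortions,
spatially varying noise, or anatomically realistic effect shapes. Passing
recovery tests on these cohorts demonstrates that the pipeline's machinery
is correct and calibrated — not that real smoking-related (or any other)
effects of a given size would be detected in real maps.

## Validation problem sizes

The package's validation suite runs at deliberately small scale so that the
complete battery executes in minutes on one CPU:

* searchlight-vs-reference equality: $6^3$ grid, 8 subjects, 4-point $C$
  grid (plus an RBF check with a joint $(C,\gamma)$ grid on a restricted
  mask);
* effect recovery: $24^3$ grid, 20 + 20 subjects, one $5^3$ cuboid region at
  $\Delta = -2 \times$ `noise_sd`, FWHM 2 voxels, 10 independent cohorts;
  the single-point grid $C = 1$ is used here since the nested search is
  exercised by the equality and structure checks; the cluster-extent filter
  is scaled to $> 10$ voxels for this grid (the default $> 50$ presumes
  brain-sized maps). Success is a permutation-FWE-surviving detection whose
  best cluster has Dice $\ge 0.5$ against the true region dilated by the
  cube radius;
* null calibration and covariate adjustment: the same grids with zero
  effect (or a pure age effect), 20 cohorts each, 499 permutations;
* LOO structure: a 37 + 28 cohort, verifying the 64/1 train/test split with
  27 features per voxel.

## Known limitations

* The searchlight is cube-shaped only; no spherical searchlight, no
  non-SVM classifiers, no feature selection.
* Parametric (random-field) cluster FWE and TFCE are out of scope.
* The binomial null treats LOO folds as independent Bernoulli trials; they
  are not, and together with the LOO pessimism described above the
  voxel-wise p-values should be read as conservative descriptive scores.
* Anatomical labeling of clusters (atlas lookup) is not provided; peak
  world-mm coordinates are.
* Voxel indices in the R API are 1-based (R convention, as in `RNifti`);
  the affine maps 0-based indices to world mm, and all conversions go
  through `voxel_to_world()`.
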