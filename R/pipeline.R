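#' Read a synthetic-cohort configuration from a YAML file
#'
#' Schema: top-level keys mirror the arguments of [synth_config()];
#' `effect_regions` is a list of mappings with keys `center`, `delta` and
#' `radius` (sphere) or `extents` (cube); `covariate_model` may contain
#' `age_slope`/`age_region` and `gender_delta`/`gender_region`.
#'
#' @param path YAML file path.
#' @return A [synth_config()] object.
#' @export
read_synth_config <- function(path) {
  synth_config_from_list(yaml::read_yaml(path))
}

synth_config_from_list <- function(lst) {
  parse_region <- function(r) {
    if (inherits(r, "effect_region")) return(r)
    effect_region(center = r$center, delta = r$delta, radius = r$radius,
                  extents = r$extents,
                  shape = if (!is.null(r$extents)) "cube" else "sphere")
  }
  if (!is.null(lst$effect_regions))
    lst$effect_regions <- lapply(lst$effect_regions, parse_region)
  if (!is.null(lst$covariate_model)) {
    for (nm in c("age_region", "gender_region"))
      if (!is.null(lst$covariate_model[[nm]]))
        lst$covariate_model[[nm]] <- parse_region(lst$covariate_model[[nm]])
  }
  do.call(synth_config, lst)
}

#' Assemble and validate a full pipeline configuration
#'
#' Exactly one of `synthetic` and `paths` must be given as the input block.
#' All stage settings have the analysis defaults: cluster-forming `p < 0.001`
#' with clusters of more than 50 voxels for the MVPA p-map and VBM, cluster
#' FWE at `p < 0.05` for the post hoc stage, 5-fold ROC cross-validation.
#'
#' @param synthetic A [synth_config()] (or plain list of its arguments).
#' @param paths List with `volumes` (vector of NIfTI paths), `mask`,
#'   `subjects` (CSV path).
#' @param searchlight A [searchlight_config()] or argument list.
#' @param statmaps List: `p_threshold`, `min_cluster_size`, `connectivity`,
#'   `chance`.
#' @param posthoc List: `cluster_forming_p`, `n_permutations`, `fwe_p`,
#'   `connectivity`, `covariates`.
#' @param vbm A [vbm_config()] or argument list.
#' @param roc List: `folds`, `threshold_rule`, `threshold`, `kernel`.
#' @param out_dir Output directory for stage artifacts.
#' @param seed Global seed; each stage derives its own stream from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, paths = NULL,
                            searchlight = searchlight_config(),
                            statmaps = list(), posthoc = list(),
                            vbm = vbm_config(), roc = list(),
                            out_dir = tempfile("searchlight_run_"), seed = 1L) {
  if (is.null(synthetic) + is.null(paths) != 1L)
    stopf("pipeline_config: exactly one of 'synthetic' and 'paths' must be given")
  if (!is.null(synthetic) && !inherits(synthetic, "synth_config"))
    synthetic <- synth_config_from_list(synthetic)
  if (!is.null(paths)) {
    need <- setdiff(c("volumes", "mask", "subjects"), names(paths))
    if (length(need)) stopf("pipeline_config: 'paths' lacks: %s", paste(need, collapse = ", "))
  }
  if (!inherits(searchlight, "searchlight_config"))
    searchlight <- do.call(searchlight_config, searchlight)
  if (!inherits(vbm, "vbm_config")) vbm <- do.call(vbm_config, vbm)
  statmaps <- utils::modifyList(list(p_threshold = 0.001, min_cluster_size = 50L,
                                     connectivity = 26L, chance = 0.5), statmaps)
  posthoc <- utils::modifyList(list(cluster_forming_p = 0.001, n_permutations = 999L,
                                    fwe_p = 0.05, connectivity = 26L,
                                    covariates = c("age", "gender")), posthoc)
  roc <- utils::modifyList(list(folds = 5L, threshold_rule = "fixed",
                                threshold = 0.5, kernel = "linear"), roc)
  structure(list(synthetic = synthetic, paths = paths, searchlight = searchlight,
                 statmaps = statmaps, posthoc = posthoc, vbm = vbm, roc = roc,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort synthesis (or loading), the searchlight
#' accuracy map, binomial p-map conversion, cluster extraction, the post hoc
#' covariate-adjusted permutation-FWE analysis inside the MVPA clusters, the
#' whole-brain VBM contrast with its signed cluster tables, ROC evaluation of
#' region-mean features for both the MVPA and the VBM region sets, and an
#' MVPA-vs-VBM overlap report.  Each stage writes its outputs into
#' `config$out_dir` before the next starts, and a reproducibility manifest
#' (configuration snapshot, per-output MD5 hashes, timestamps) is written
#' last.
#'
#' Stage seeds are derived as `hash(global seed, stage name)`, so adding
#' stages never shifts the random streams of earlier ones; re-running an
#' identical configuration reproduces identical output hashes.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return The manifest (list), invisibly; all stage outputs are on disk under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (!inherits(config, "pipeline_config")) stopf("run_pipeline: 'config' must be a pipeline_config")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  outputs <- character()
  run_stage <- function(name, expr) {
    say("stage %s ...", name)
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  cohort <- run_stage("input", {
    if (!is.null(config$synthetic)) generate_cohort(config$synthetic)
    else load_cohort(config$paths$volumes, config$paths$mask, config$paths$subjects)
  })
  save_map(array(as.numeric(cohort$mask), grid_shape(cohort)), cohort$affine,
           outputs["mask"] <- file.path(out, "mask.nii"))
  utils::write.csv(cohort$subjects, outputs["subjects"] <- file.path(out, "subjects.csv"),
                   row.names = FALSE)

  slmap <- run_stage("searchlight", {
    cfg <- config$searchlight
    cfg$seed <- stage_seed(config$seed, "searchlight")
    searchlight_map(cohort, cfg, verbose = verbose)
  })
  save_map(slmap$accuracy, cohort$affine,
           outputs["accuracy"] <- file.path(out, "accuracy.nii"))

  pmap <- run_stage("pmap", pvalue_map(slmap, chance = config$statmaps$chance))
  save_map(pmap$p, cohort$affine, outputs["pmap"] <- file.path(out, "pmap.nii"))

  mvpa_clusters <- run_stage("clusters", {
    extract_clusters(pmap, p_threshold = config$statmaps$p_threshold,
                     min_cluster_size = config$statmaps$min_cluster_size,
                     connectivity = config$statmaps$connectivity)
  })
  write_cluster_table(mvpa_clusters,
                      outputs["mvpa_clusters"] <- file.path(out, "mvpa_clusters.tsv"))

  posthoc <- run_stage("posthoc", {
    if (nrow(mvpa_clusters) == 0L) {
      say("posthoc skipped: no MVPA clusters")
      NULL
    } else {
      adjusted <- regress_covariates(cohort, config$posthoc$covariates)
      cluster_fwe_permutation(adjusted, analysis_mask = cluster_mask(mvpa_clusters),
                              cluster_forming_p = config$posthoc$cluster_forming_p,
                              connectivity = config$posthoc$connectivity,
                              n_permutations = config$posthoc$n_permutations,
                              fwe_p = config$posthoc$fwe_p,
                              seed = stage_seed(config$seed, "posthoc"))
    }
  })
  if (!is.null(posthoc)) {
    save_map(posthoc$t_map$t, cohort$affine,
             outputs["posthoc_tmap"] <- file.path(out, "posthoc_tmap.nii"))
    write_cluster_table(posthoc$clusters,
                        outputs["posthoc_clusters"] <- file.path(out, "posthoc_clusters.tsv"))
  }

  vbm_t <- run_stage("vbm", wholebrain_tmap(cohort, config$vbm))
  save_map(vbm_t$t, cohort$affine, outputs["vbm_tmap"] <- file.path(out, "vbm_tmap.nii"))
  vbm_tab <- run_stage("vbm_clusters", vbm_clusters(vbm_t, config$vbm, affine = cohort$affine))
  write_cluster_table(vbm_tab$case_lower,
                      outputs["vbm_clusters_lower"] <- file.path(out, "vbm_clusters_lower.tsv"))
  write_cluster_table(vbm_tab$case_higher,
                      outputs["vbm_clusters_higher"] <- file.path(out, "vbm_clusters_higher.tsv"))

  roc_one <- function(clusters, name) {
    has <- if (inherits(clusters, "cluster_table")) nrow(clusters) > 0L
           else any(vapply(clusters, nrow, integer(1)) > 0L)
    if (!has) {
      say("roc (%s) skipped: no clusters", name)
      return(NULL)
    }
    feats <- region_mean_features(cohort, clusters)
    rep <- cv_predicted_probabilities(feats, folds = config$roc$folds,
                                      seed = stage_seed(config$seed, paste0("roc_", name)),
                                      kernel = config$roc$kernel)
    rep <- roc_metrics(rep, threshold_rule = config$roc$threshold_rule,
                       threshold = config$roc$threshold)
    path <- file.path(out, sprintf("roc_%s.json", name))
    jsonlite::write_json(list(auc = rep$auc, sensitivity = rep$sensitivity,
                              specificity = rep$specificity, ppv = rep$ppv,
                              npv = rep$npv, threshold = rep$threshold),
                         path, auto_unbox = TRUE, digits = NA)
    outputs[sprintf("roc_%s", name)] <<- path
    utils::write.csv(rep$samples, file.path(out, sprintf("roc_%s_probabilities.csv", name)),
                     row.names = FALSE)
    rep
  }
  roc_mvpa <- run_stage("roc_mvpa", roc_one(mvpa_clusters, "mvpa"))
  roc_vbm <- run_stage("roc_vbm",
                       roc_one(list(vbm_tab$case_lower, vbm_tab$case_higher), "vbm"))

  comparison <- run_stage("compare", {
    cmp <- compare_methods(mvpa_clusters, vbm_tab, mask = cohort$mask)
    jsonlite::write_json(cmp[c("dice", "n_mvpa_voxels", "n_vbm_voxels",
                               "n_overlap", "n_mvpa_only", "n_vbm_only")],
                         outputs["compare"] <- file.path(out, "compare.json"),
                         auto_unbox = TRUE, digits = NA)
    cmp
  })

  manifest <- list(
    package_version = as.character(packageVersion("searchlight")),
    seed = config$seed,
    config = config_snapshot(config),
    outputs = lapply(as.list(outputs), function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p)))),
    results = list(
      n_mvpa_clusters = nrow(mvpa_clusters),
      n_posthoc_surviving = if (is.null(posthoc)) 0L else sum(posthoc$clusters$surviving),
      n_vbm_clusters = nrow(vbm_tab$case_lower) + nrow(vbm_tab$case_higher),
      mvpa_auc = if (is.null(roc_mvpa)) NA else roc_mvpa$auc,
      vbm_auc = if (is.null(roc_vbm)) NA else roc_vbm$auc,
      dice = comparison$dice),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  say("pipeline complete: %s", out)
  invisible(manifest)
}

# JSON-serializable snapshot of a pipeline_config (drops volume paths' data).
config_snapshot <- function(config) {
  snap <- unclass(config)
  if (!is.null(snap$synthetic)) {
    s <- unclass(snap$synthetic)
    s$effect_regions <- lapply(s$effect_regions, unclass)
    if (!is.null(s$covariate_model))
      s$covariate_model <- lapply(s$covariate_model, function(v)
        if (inherits(v, "effect_region")) unclass(v) else v)
    snap$synthetic <- s
  }
  snap$searchlight <- unclass(snap$searchlight)
  snap$vbm <- unclass(snap$vbm)
  snap
}

#' Overlap report between MVPA and VBM detections
#'
#' Computes the Dice coefficient between the voxel sets detected by the two
#' methods, the voxel counts unique to each, and a per-cluster best-overlap
#' matching.  No directional claim is made: the report only tabulates the
#' overlap.
#'
#' @param mvpa_clusters A `cluster_table` from the MVPA branch.
#' @param vbm_clusters A `vbm_clusters` object or a `cluster_table`.
#' @param mask Optional cohort mask used only for grid validation.
#' @return List with `dice`, voxel counts, and a `matching` data frame
#'   (per MVPA cluster: best-overlapping VBM cluster and shared voxels).
#' @export
compare_methods <- function(mvpa_clusters, vbm_clusters, mask = NULL) {
  m_lab <- attr(mvpa_clusters, "labels")
  if (inherits(vbm_clusters, "vbm_clusters")) {
    v_mask <- cluster_mask(list(vbm_clusters$case_lower, vbm_clusters$case_higher))
    v_lab <- attr(vbm_clusters$case_lower, "labels")
    v_lab2 <- attr(vbm_clusters$case_higher, "labels")
    off <- max(0L, v_lab)
    v_lab <- v_lab + ifelse(v_lab2 > 0L, off + v_lab2, 0L)
  } else {
    v_lab <- attr(vbm_clusters, "labels")
    v_mask <- v_lab > 0
  }
  if (!identical(dim(m_lab), dim(v_lab)))
    stopf("compare_methods: cluster grids do not match")
  if (!is.null(mask) && !identical(dim(mask), dim(m_lab)))
    stopf("compare_methods: mask grid does not match the cluster grids")
  m_mask <- m_lab > 0
  inter <- m_mask & v_mask
  matching <- do.call(rbind, lapply(seq_len(max(0L, m_lab)), function(id) {
    vox <- which(m_lab == id)
    hits <- v_lab[vox]
    hits <- hits[hits > 0]
    best <- if (length(hits)) as.integer(names(which.max(table(hits)))) else NA_integer_
    data.frame(mvpa_cluster = id, best_vbm_cluster = best,
               shared_voxels = length(hits), mvpa_size = length(vox))
  }))
  list(dice = dice_coefficient(m_mask, v_mask),
       n_mvpa_voxels = sum(m_mask), n_vbm_voxels = sum(v_mask),
       n_overlap = sum(inter),
       n_mvpa_only = sum(m_mask & !v_mask), n_vbm_only = sum(v_mask & !m_mask),
       matching = if (is.null(matching))
         data.frame(mvpa_cluster = integer(), best_vbm_cluster = integer(),
                    shared_voxels = integer(), mvpa_size = integer())
       else matching)
}
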