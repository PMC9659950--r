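#' Default configuration for a full synthetic-cohort analysis
#'
#' @param spec A [cohort_spec] (default: package defaults).
#' @param out_dir Optional output directory; `NULL` keeps everything in
#'   memory.
#' @param seed Master seed recorded in the manifest and used for every
#'   stochastic stage.
#' @return Named list of run parameters.
#' @export
default_run_config <- function(spec = cohort_spec(), out_dir = NULL,
                               seed = 1) {
  list(spec = spec, out_dir = out_dir, seed = as.integer(seed),
       k_discard = 10, low_hz = 0.01, high_hz = 0.08,
       fd_sd_threshold = 2.5, fwhm_mm = 6,
       voxel_p = 0.005, cluster_alpha = 0.05, connectivity = 26,
       prune_threshold = 0.75, n_perm = 200, perm_grid = c(0, 1))
}

#' Load a run configuration from a YAML file
#'
#' Scalar parameters override [default_run_config()]; the cohort spec
#' fields live under a `spec:` block.
#'
#' @param path YAML file path.
#' @return Run configuration list.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the `yaml` package is required to read YAML configurations")
  y <- yaml::read_yaml(path)
  spec_args <- y$spec %||% list()
  spec <- do.call(cohort_spec, spec_args)
  cfg <- default_run_config(spec, y$out_dir, y$seed %||% 1)
  for (k in setdiff(names(y), c("spec", "out_dir", "seed")))
    cfg[[k]] <- y[[k]]
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis on a synthetic cohort
#'
#' Executes the study's stage order end to end: simulate the cohort;
#' preprocess every subject (volume discard, band-pass, nuisance
#' regression) with framewise-displacement QC; compute smoothed
#' z-standardised ReHo maps; find group-difference clusters with GRF
#' correction; use surviving ReHo clusters as seeds for whole-brain
#' z-FC maps; find FC group-difference clusters; assemble per-cluster
#' mean features; classify with pruning + grid-searched LOOCV logistic
#' regression and a permutation test; and tabulate clinical group
#' statistics. If the ReHo stage yields no significant clusters, the FC
#' and classification stages are skipped and the run reports
#' `"no ROIs"` rather than failing.
#'
#' @param config List from [default_run_config()] or
#'   [read_run_config()].
#' @param cohort Optional pre-generated `synthetic_cohort` (otherwise
#'   generated from `config$spec`).
#' @return List of class `rehoflow_run`: per-stage results and a
#'   `manifest` describing outputs, seeds and (when written) file
#'   hashes.
#' @export
run_full_analysis <- function(config = default_run_config(), cohort = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  spec <- config$spec
  if (is.null(cohort)) {
    spec$rng_seed <- config$seed
    spec <- validate_cohort_spec(spec)
    cohort <- stage("simulate", generate_cohort(spec))
  }
  n <- length(cohort$volumes)
  groups <- cohort$groups

  # motion QC on the undiscarded traces
  mean_fd <- vapply(cohort$motion, function(m)
    mean(framewise_displacement(m)), 1)
  excluded <- stage("motion_qc",
                    flag_motion_exclusions(mean_fd, config$fd_sd_threshold))
  keep <- which(!excluded)

  preproc <- stage("preprocess", lapply(keep, function(i)
    preprocess_subject(cohort$volumes[[i]], cohort$motion[[i]],
                       wm_mask = spec$wm_mask, csf_mask = spec$csf_mask,
                       k_discard = config$k_discard,
                       low_hz = config$low_hz, high_hz = config$high_hz)))
  groups_kept <- groups[keep]

  reho_maps <- stage("reho", lapply(preproc, function(v)
    reho_pipeline(v, fwhm_mm = config$fwhm_mm)$smz))
  reho_test <- stage("group_reho", voxelwise_ttest(
    reho_maps[groups_kept == 1], reho_maps[groups_kept == 2]))
  reho_grf <- stage("group_reho", grf_cluster_threshold(
    reho_test, voxel_p = config$voxel_p,
    cluster_alpha = config$cluster_alpha,
    connectivity = config$connectivity,
    voxel_size_mm = spec$voxel_size_mm))

  result <- list(cohort = cohort, mean_fd = mean_fd, excluded = excluded,
                 reho_maps = reho_maps, reho_clusters = reho_grf,
                 config = config)

  if (length(reho_grf$clusters) == 0) {
    result$status <- "no ROIs"
    result$manifest <- run_manifest(result)
    class(result) <- "rehoflow_run"
    return(result)
  }
  result$status <- "complete"

  rois <- lapply(reho_grf$clusters, define_roi_from_cluster,
                 dims = spec$grid_shape)
  names(rois) <- sprintf("reho_cluster%d", seq_along(rois))
  smoothed <- stage("fc", lapply(preproc, smooth_gaussian,
                                 fwhm_mm = config$fwhm_mm))
  zfc <- stage("fc", fc_pipeline(smoothed, rois))
  fc_grf <- list()
  fc_maps_by_roi <- list()
  for (rn in names(rois)) {
    maps <- lapply(zfc, `[[`, rn)
    # exclude the seed's own voxels from the FC contrast mask
    fcmask <- maps[[1]]$mask & !rois[[rn]]
    tt <- voxelwise_ttest(maps[groups_kept == 1], maps[groups_kept == 2],
                          mask = fcmask)
    fc_grf[[rn]] <- grf_cluster_threshold(
      tt, voxel_p = config$voxel_p, cluster_alpha = config$cluster_alpha,
      connectivity = config$connectivity,
      voxel_size_mm = spec$voxel_size_mm)
    fc_maps_by_roi[[rn]] <- maps
  }
  result$fc_clusters <- fc_grf

  # features: per-cluster mean szReHo + per-cluster mean z-FC
  feat_list <- list()
  for (ci in seq_along(rois))
    feat_list[[sprintf("reho_c%d", ci)]] <-
      vapply(reho_maps, function(m) mean(m$values[rois[[ci]]]), 1)
  for (rn in names(fc_grf)) {
    cls <- fc_grf[[rn]]$clusters
    for (ci in seq_along(cls)) {
      roi <- define_roi_from_cluster(cls[[ci]], spec$grid_shape)
      feat_list[[sprintf("fc_%s_c%d", rn, ci)]] <-
        vapply(fc_maps_by_roi[[rn]], function(m) mean(m$values[roi]), 1)
    }
  }
  features <- as.data.frame(feat_list)
  labels <- factor(ifelse(groups_kept == 1, "MCI", "nMCI"),
                   levels = c("nMCI", "MCI"))
  report <- stage("classify", classify_subjects(
    features, labels, config$prune_threshold))
  perm <- stage("classify", permutation_test(
    features, labels, n_perm = config$n_perm, seed = config$seed,
    prune_threshold = config$prune_threshold, grid = config$perm_grid))
  report$permutation_p <- perm$p
  report$n_perm <- perm$n_perm
  result$features <- features
  result$labels <- labels
  result$classifier <- report

  result$clinical_table <- stage("clinical", clinical_group_table(
    cohort$clinical[keep, , drop = FALSE]))
  result$manifest <- run_manifest(result)
  class(result) <- "rehoflow_run"
  if (!is.null(config$out_dir)) write_run_outputs(result, config$out_dir)
  result
}

run_manifest <- function(result) {
  cfg <- result$config
  list(status = result$status,
       seed = cfg$seed,
       n_subjects = length(result$cohort$volumes),
       n_excluded = sum(result$excluded),
       n_reho_clusters = length(result$reho_clusters$clusters),
       n_fc_clusters = if (is.null(result$fc_clusters)) 0 else
         sum(vapply(result$fc_clusters,
                    function(g) length(g$clusters), 1L)),
       parameters = cfg[setdiff(names(cfg), c("spec", "out_dir"))])
}

write_run_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$reho_clusters$table,
                   file.path(dir, "reho_clusters.csv"), row.names = FALSE)
  if (!is.null(result$fc_clusters)) {
    fc_tab <- do.call(rbind, lapply(names(result$fc_clusters), function(rn) {
      tb <- result$fc_clusters[[rn]]$table
      if (nrow(tb)) cbind(roi = rn, tb)
    }))
    if (!is.null(fc_tab))
      utils::write.csv(fc_tab, file.path(dir, "fc_clusters.csv"),
                       row.names = FALSE)
  }
  if (!is.null(result$features))
    utils::write.csv(cbind(result$features, label = result$labels),
                     file.path(dir, "features.csv"), row.names = FALSE)
  if (!is.null(result$clinical_table))
    utils::write.csv(result$clinical_table,
                     file.path(dir, "clinical_stats.csv"), row.names = FALSE)
  man <- result$manifest
  files <- list.files(dir, full.names = TRUE)
  man$files <- lapply(files, function(f)
    list(path = basename(f), md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.rehoflow_run <- function(x, ...) {
  cat(sprintf("<rehoflow_run> status: %s | %d subjects (%d excluded)\n",
              x$status, length(x$cohort$volumes), sum(x$excluded)))
  cat(sprintf("  ReHo clusters: %d\n", length(x$reho_clusters$clusters)))
  if (!is.null(x$fc_clusters))
    cat(sprintf("  FC clusters: %d\n",
                sum(vapply(x$fc_clusters, function(g) length(g$clusters), 1L))))
  if (!is.null(x$classifier)) print(x$classifier)
  invisible(x)
}
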