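#!/usr/bin/env Rscript
# Step 6: group differences in seed-based connectivity, per seed ROI,
# with the same GRF cluster-level correction as the ReHo contrast.

source("analysis/00_config.R")

spec <- analysis_spec()
groups <- jsonlite::read_json(file.path(cohort_dir, "ground_truth.json"),
                              simplifyVector = TRUE)$groups
qc <- read.csv(file.path(results_dir, "motion_qc.csv"))
kept <- qc$id[!qc$excluded]
groups <- groups[!qc$excluded]

roi_files <- sort(list.files(derived_dir, pattern = "^roi_reho_c\\d+\\.nii\\.gz$"))
all_tabs <- list()
for (rf in roi_files) {
  rn <- sub("^roi_(.*)\\.nii\\.gz$", "\\1", rf)
  roi <- read_nifti_volume(file.path(derived_dir, rf))$values > 0
  maps <- lapply(kept, function(id)
    read_nifti_volume(file.path(derived_dir,
                                sprintf("%s_zfc_%s.nii.gz", id, rn)),
                      mask = file.path(cohort_dir, "mask.nii.gz")))
  fcmask <- maps[[1]]$mask & !roi         # seed voxels excluded
  tt <- voxelwise_ttest(maps[groups == 1], maps[groups == 2], mask = fcmask)
  grf <- grf_cluster_threshold(tt, voxel_p = run_params$voxel_p,
                               cluster_alpha = run_params$cluster_alpha,
                               voxel_size_mm = spec$voxel_size_mm)
  message(sprintf("seed %s: %d surviving FC cluster(s)", rn,
                  length(grf$clusters)))
  if (nrow(grf$table)) all_tabs[[rn]] <- cbind(roi = rn, grf$table)
  for (i in seq_along(grf$clusters)) {
    cl_roi <- define_roi_from_cluster(grf$clusters[[i]], spec$grid_shape)
    write_nifti_volume(stat_map(array(as.numeric(cl_roi), spec$grid_shape),
                                cl_roi, tt$tmap$affine),
                       file.path(derived_dir,
                                 sprintf("roi_fc_%s_c%d.nii.gz", rn, i)))
  }
}
tab <- if (length(all_tabs)) do.call(rbind, all_tabs) else
  data.frame(roi = character())
write.csv(tab, file.path(results_dir, "fc_clusters.csv"), row.names = FALSE)
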