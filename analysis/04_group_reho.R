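#!/usr/bin/env Rscript
# Step 4: voxelwise two-sample t-test on szReHo maps with GRF
# cluster-level correction (voxel p < 0.005, cluster p < 0.05).
# Surviving clusters become the seed ROIs for the connectivity step.

source("analysis/00_config.R")

spec <- analysis_spec()
groups <- jsonlite::read_json(file.path(cohort_dir, "ground_truth.json"),
                              simplifyVector = TRUE)$groups
qc <- read.csv(file.path(results_dir, "motion_qc.csv"))
kept <- qc$id[!qc$excluded]
groups <- groups[!qc$excluded]

maps <- lapply(kept, function(id)
  read_nifti_volume(file.path(derived_dir, paste0(id, "_szreho.nii.gz")),
                    mask = file.path(cohort_dir, "mask.nii.gz")))
tt <- voxelwise_ttest(maps[groups == 1], maps[groups == 2])
grf <- grf_cluster_threshold(tt, voxel_p = run_params$voxel_p,
                             cluster_alpha = run_params$cluster_alpha,
                             voxel_size_mm = spec$voxel_size_mm)
print(grf)
write.csv(grf$table, file.path(results_dir, "reho_clusters.csv"),
          row.names = FALSE)
write_nifti_volume(grf_thresholded_map(grf, tt),
                   file.path(derived_dir, "reho_tmap_thresholded.nii.gz"))
for (i in seq_along(grf$clusters)) {
  roi <- define_roi_from_cluster(grf$clusters[[i]], spec$grid_shape)
  write_nifti_volume(stat_map(array(as.numeric(roi), spec$grid_shape),
                              roi, tt$tmap$affine),
                     file.path(derived_dir, sprintf("roi_reho_c%d.nii.gz", i)))
}
message(sprintf("%d ReHo cluster(s) written as seed ROIs",
                length(grf$clusters)))
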