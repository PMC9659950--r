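#!/usr/bin/env Rscript
# Step 7: classify MCI vs nMCI from per-cluster mean szReHo and z-FC
# features: collinearity pruning (|r| > 0.75), ridge-penalty grid
# search, LOOCV, permutation validation.

source("analysis/00_config.R")

spec <- analysis_spec()
groups <- jsonlite::read_json(file.path(cohort_dir, "ground_truth.json"),
                              simplifyVector = TRUE)$groups
qc <- read.csv(file.path(results_dir, "motion_qc.csv"))
kept <- qc$id[!qc$excluded]
groups <- groups[!qc$excluded]
mask_path <- file.path(cohort_dir, "mask.nii.gz")

reho_maps <- lapply(kept, function(id)
  read_nifti_volume(file.path(derived_dir, paste0(id, "_szreho.nii.gz")),
                    mask = mask_path))
feat <- list()
for (rf in sort(list.files(derived_dir, pattern = "^roi_reho_c\\d+\\.nii\\.gz$"))) {
  rn <- sub("^roi_(.*)\\.nii\\.gz$", "\\1", rf)
  roi <- read_nifti_volume(file.path(derived_dir, rf))$values > 0
  feat[[rn]] <- vapply(reho_maps, function(m) mean(m$values[roi]), 1)
}
for (rf in sort(list.files(derived_dir, pattern = "^roi_fc_.*\\.nii\\.gz$"))) {
  cn <- sub("^roi_(fc_.*)\\.nii\\.gz$", "\\1", rf)
  seed <- sub("^fc_(reho_c\\d+)_c\\d+$", "\\1", cn)
  roi <- read_nifti_volume(file.path(derived_dir, rf))$values > 0
  feat[[cn]] <- vapply(kept, function(id) {
    m <- read_nifti_volume(file.path(derived_dir,
                                     sprintf("%s_zfc_%s.nii.gz", id, seed)),
                           mask = mask_path)
    mean(m$values[roi])
  }, 1)
}
features <- as.data.frame(feat)
labels <- factor(ifelse(groups == 1, "MCI", "nMCI"), c("nMCI", "MCI"))
write.csv(cbind(id = kept, features, label = labels),
          file.path(results_dir, "features.csv"), row.names = FALSE)

report <- classify_subjects(features, labels,
                            prune_threshold = run_params$prune_threshold)
perm <- permutation_test(features, labels, n_perm = run_params$n_perm,
                         seed = master_seed,
                         prune_threshold = run_params$prune_threshold)
report$permutation_p <- perm$p
report$n_perm <- perm$n_perm
print(report)
write.csv(report$roc, file.path(results_dir, "roc_points.csv"),
          row.names = FALSE)
jsonlite::write_json(
  list(auc = report$auc, accuracy = report$accuracy,
       sensitivity = report$sensitivity, specificity = report$specificity,
       kappa = report$kappa, permutation_p = report$permutation_p,
       n_perm = report$n_perm, lambda = report$lambda,
       kept_features = report$kept_features),
  file.path(results_dir, "classifier_report.json"),
  auto_unbox = TRUE, digits = NA)
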