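#!/usr/bin/env Rscript
# Step 5: seed-based whole-brain functional connectivity. Each ReHo
# cluster from step 4 seeds a Pearson correlation map on the smoothed
# residual volumes; maps are Fisher r-to-z transformed per subject.

source("analysis/00_config.R")

spec <- analysis_spec()
roi_files <- sort(list.files(derived_dir, pattern = "^roi_reho_c\\d+\\.nii\\.gz$"))
if (length(roi_files) == 0) {
  message("no seed ROIs from step 4 ('no ROIs'): skipping connectivity")
  quit(save = "no", status = 0)
}
rois <- lapply(roi_files, function(f)
  read_nifti_volume(file.path(derived_dir, f))$values > 0)
names(rois) <- sub("^roi_(.*)\\.nii\\.gz$", "\\1", roi_files)

qc <- read.csv(file.path(results_dir, "motion_qc.csv"))
kept <- qc$id[!qc$excluded]
for (id in kept) {
  vol <- read_nifti_volume(file.path(derived_dir, paste0(id, "_clean.nii.gz")),
                           mask = file.path(cohort_dir, "mask.nii.gz"),
                           tr = spec$tr)
  vol <- smooth_gaussian(vol, run_params$fwhm_mm)
  zmaps <- fc_pipeline(list(vol), rois)[[1]]
  for (rn in names(zmaps))
    write_nifti_volume(zmaps[[rn]],
                       file.path(derived_dir,
                                 sprintf("%s_zfc_%s.nii.gz", id, rn)))
}
message(sprintf("z-FC maps written for %d subjects x %d ROIs",
                length(kept), length(rois)))
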