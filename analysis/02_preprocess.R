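#!/usr/bin/env Rscript
# Step 2: motion QC and the functional preprocessing chain
# (discard -> band-pass -> Friston-24 + WM/CSF nuisance regression).
# Writes a QC table and per-subject residual volumes.

source("analysis/00_config.R")

spec <- analysis_spec()
subs <- sort(list.files(cohort_dir, pattern = "_bold\\.nii\\.gz$"))
ids <- sub("_bold\\.nii\\.gz$", "", subs)

mean_fd <- vapply(ids, function(id) {
  mot <- as.matrix(read.delim(file.path(cohort_dir, paste0(id, "_motion.tsv"))))
  mean(framewise_displacement(mot))
}, 1)
excluded <- flag_motion_exclusions(mean_fd)
qc <- data.frame(id = ids, mean_fd = mean_fd, excluded = excluded)
write.csv(qc, file.path(results_dir, "motion_qc.csv"), row.names = FALSE)
message(sprintf("motion QC: %d/%d subjects excluded (mean FD > mean + 2.5 SD)",
                sum(excluded), length(ids)))

dir.create(derived_dir, showWarnings = FALSE, recursive = TRUE)
for (id in ids[!excluded]) {
  vol <- read_nifti_volume(file.path(cohort_dir, paste0(id, "_bold.nii.gz")),
                           mask = file.path(cohort_dir, "mask.nii.gz"),
                           tr = spec$tr)
  mot <- as.matrix(read.delim(file.path(cohort_dir, paste0(id, "_motion.tsv"))))
  pp <- preprocess_subject(vol, mot, wm_mask = spec$wm_mask,
                           csf_mask = spec$csf_mask,
                           k_discard = run_params$k_discard,
                           low_hz = run_params$low_hz,
                           high_hz = run_params$high_hz)
  write_nifti_volume(pp, file.path(derived_dir, paste0(id, "_clean.nii.gz")))
}
message("preprocessed volumes written to ", derived_dir)
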