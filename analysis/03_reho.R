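#!/usr/bin/env Rscript
# Step 3: voxelwise regional homogeneity per subject -- raw Kendall's W
# over 27-voxel neighbourhoods, divided by the in-mask global mean,
# smoothed 6 mm and z-standardised (szReHo).

source("analysis/00_config.R")

spec <- analysis_spec()
ids <- sub("_clean\\.nii\\.gz$", "",
           sort(list.files(derived_dir, pattern = "_clean\\.nii\\.gz$")))
for (id in ids) {
  vol <- read_nifti_volume(file.path(derived_dir, paste0(id, "_clean.nii.gz")),
                           mask = file.path(cohort_dir, "mask.nii.gz"),
                           tr = spec$tr)
  maps <- reho_pipeline(vol, fwhm_mm = run_params$fwhm_mm)
  write_nifti_volume(maps$smz,
                     file.path(derived_dir, paste0(id, "_szreho.nii.gz")))
}
message(sprintf("szReHo maps written for %d subjects", length(ids)))
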