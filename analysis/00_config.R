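# Shared settings for the analysis workflow (sourced by every step).
#
# The cohort emulates the target study design at desk scale: two groups
# of male OSA patients with/without mild cognitive impairment, 240
# BOLD volumes at TR = 2 s on a 3 mm grid, with reduced local synchrony
# planted in two regions of the impaired group and weakened seed-target
# coupling. Group sizes are reduced from 48/47 to 20/20 to keep the
# workflow runnable on a laptop; all statistical machinery is identical.

library(rehoflow)

cohort_dir  <- "scratch/analysis/cohort"      # NIfTI + TSV intermediates
derived_dir <- "scratch/analysis/derived"     # preprocessed maps
results_dir <- "results"                      # tables and reports

master_seed <- 20260926L

analysis_spec <- function() {
  cohort_spec(n_group1 = 20, n_group2 = 20, n_timepoints = 240,
              rng_seed = master_seed)
}

run_params <- list(k_discard = 10, low_hz = 0.01, high_hz = 0.08,
                   fwhm_mm = 6, voxel_p = 0.005, cluster_alpha = 0.05,
                   prune_threshold = 0.75, n_perm = 500)

dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)
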