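#!/usr/bin/env Rscript
# Step 1: generate the synthetic cohort (BOLD volumes, motion traces,
# clinical table, ground truth) and write it to disk.

source("analysis/00_config.R")

spec <- analysis_spec()
message(sprintf("simulating %d + %d subjects, %d volumes, %s grid",
                spec$n_group1, spec$n_group2, spec$n_timepoints,
                paste(spec$grid_shape, collapse = "x")))

cohort <- generate_cohort(spec)
write_cohort(cohort, cohort_dir)

# clinical table is also a primary output of the simulation step
write.table(cohort$clinical, file.path(results_dir, "clinical_table.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

message("planted effects:")
for (er in cohort$ground_truth$effect_regions)
  message(sprintf("  region of %d voxels, synchrony drop %.2f (group 1)",
                  sum(er$mask), er$drop))
message(sprintf("  seed-target coupling r = %.2f (group 1) vs %.2f (group 2)",
                spec$seed_coupling$r[1], spec$seed_coupling$r[2]))
message("wrote cohort to ", cohort_dir)
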