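#!/usr/bin/env Rscript
# Step 8: non-imaging statistics -- the power analysis behind the
# design, group comparisons of the clinical table (normality-gated
# t / Mann-Whitney with Bonferroni adjustment), and correlations of
# MoCA with clinical variables.

source("analysis/00_config.R")

power <- required_sample_size(effect_size_d = 0.8, alpha = 0.05, power = 0.8)
message(sprintf("power analysis (d = 0.8, alpha = 0.05, power = 0.8): %d per group, total %d",
                power$n_per_group, power$total))

clin <- read.delim(file.path(results_dir, "clinical_table.tsv"))
tab <- clinical_group_table(clin)
write.csv(tab, file.path(results_dir, "clinical_stats.csv"),
          row.names = FALSE)
print(tab[, c("variable", "test", "p", "p_bonferroni")], row.names = FALSE)

# correlations of cognition with clinical variables across all subjects
vars <- setdiff(names(clin)[vapply(clin, is.numeric, TRUE)], "moca")
corr <- do.call(rbind, lapply(vars, function(v) {
  ct <- pearson_corr_test(clin$moca, clin[[v]])
  data.frame(variable = v, r = ct$r, p = ct$p)
}))
corr$p_bonferroni <- bonferroni_adjust(corr$p, m = nrow(corr))
write.csv(corr, file.path(results_dir, "moca_correlations.csv"),
          row.names = FALSE)
message("clinical statistics written to ", results_dir)
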