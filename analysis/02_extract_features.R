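#!/usr/bin/env Rscript
# Extract the 183-feature catalogue from every scan of the simulated cohort
# (reading the NIfTI files written by 01_simulate_cohort.R) and write the
# pre- and post-treatment feature tables.

library(deltarad)

manifest_csv <- "scratch/cohort/cohort_manifest.csv"
if (!file.exists(manifest_csv))
  stop("run analysis/01_simulate_cohort.R first")
dir.create("results", showWarnings = FALSE)

cohort <- read_cohort(manifest_csv)
message("Extracting 183 features x 2 time points for ", length(cohort),
        " subjects (takes a few minutes) ...")
pre <- cohort_feature_table(cohort, default_manifest(), "pre")
post <- cohort_feature_table(cohort, default_manifest(), "post")

write.csv(as.data.frame(pre), "results/features_pre.csv", row.names = FALSE)
write.csv(as.data.frame(post), "results/features_post.csv", row.names = FALSE)
message("Wrote results/features_pre.csv and results/features_post.csv (",
        ncol(pre) - 2, " features each)")
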