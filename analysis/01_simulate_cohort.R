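#!/usr/bin/env Rscript
# Simulate the synthetic study: 20 mutant + 20 wild-type subjects with
# baseline/follow-up lesion CT phantoms (1 mm grid, 64^3, semi-axes 5-15 mm),
# plus 20 same-day test-retest pairs. Volumes are written as NIfTI under
# scratch/ (they are bulky and reproducible); the cohort manifest CSV is the
# interface the rest of the workflow reads.

library(deltarad)

cohort_seed <- 7
retest_seed <- 11
out_dir <- "scratch/cohort"

message("Generating 20 + 20 subject cohort (seed ", cohort_seed, ") ...")
cohort <- generate_cohort(n_mutant = 20, n_wt = 20, seed = cohort_seed)
manifest <- write_cohort(cohort, out_dir)
message("Wrote ", length(cohort), " subjects to ", manifest)

ratios <- sapply(cohort, function(s) tumor_volume(s$post$mask) / tumor_volume(s$pre$mask))
labels <- sapply(cohort, `[[`, "label")
message(sprintf("Mean post/pre volume ratio: mutant %.2f, wild-type %.2f",
                mean(ratios[labels == 1]), mean(ratios[labels == 0])))

message("Generating 20 test-retest pairs (seed ", retest_seed, ") ...")
pairs <- generate_test_retest(20, seed = retest_seed)
pair_dir <- "scratch/retest"
dir.create(pair_dir, recursive = TRUE, showWarnings = FALSE)
rows <- lapply(pairs, function(p) {
  f <- function(tag, obj) {
    path <- file.path(pair_dir, sprintf("%s_%s.nii.gz", p$subject_id, tag))
    write_volume(obj, path)
    basename(path)
  }
  data.frame(subject_id = p$subject_id,
             scan1_image = f("scan1", p$scan1$image),
             scan1_mask = f("scan1_mask", p$scan1$mask),
             scan2_image = f("scan2", p$scan2$image),
             scan2_mask = f("scan2_mask", p$scan2$mask))
})
write.csv(do.call(rbind, rows), file.path(pair_dir, "retest_manifest.csv"),
          row.names = FALSE)
message("Wrote test-retest pairs to ", pair_dir)
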