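#!/usr/bin/env Rscript

# Stage 1 -- simulate the study cohort.
#
# Draws 80 synthetic DSC-PWI series (50 timepoints each) with ellipsoidal
# lesions and mirrored normal-tissue masks, a clinical table matching the
# published cohort marginals, and 7-level 90-day mRS labels whose latent
# score depends on age, admission NIHSS, lesion volume and the per-patient
# perfusion deficit. Writes a compact summary plus one example series to
# results/; downstream stages regenerate the cohort from the same seed, so
# nothing large needs to persist.

suppressMessages(library(perfrad))

seed <- 2026L
dir.create("results", showWarnings = FALSE)

cfg <- synth_config(n_patients = 80L, n_timepoints = 50L,
                    volume_shape = c(6L, 16L, 16L), seed = seed)
coh <- generate_cohort(cfg)

cat(sprintf("cohort: %d series, %d timepoints, volume %s\n",
            length(coh$series), cfg$n_timepoints,
            paste(cfg$volume_shape, collapse = "x")))
cat("mRS_7 distribution:\n")
print(table(factor(coh$mrs7, levels = 0:6)))

utils::write.csv(coh$cti, "results/cohort_cti.csv", row.names = FALSE)
utils::write.csv(data.frame(sample = seq_along(coh$mrs7), mrs7 = coh$mrs7,
                            perfusion_deficit = coh$truth$perfusion_deficit),
                 "results/cohort_labels.csv", row.names = FALSE)
dir.create("scratch", showWarnings = FALSE)
write_series(coh$series[[1]], "scratch/example_series.nii.gz")
write_mask(coh$rois[[1]]$lt_mask, "scratch/example_lt_mask.nii.gz")

cat("age:", round(mean(coh$cti$age), 1), "+/-", round(sd(coh$cti$age), 1),
    "years;", sum(coh$cti$sex_female), "female\n")
cat("wrote results/cohort_cti.csv, results/cohort_labels.csv and one",
    "example series/mask pair under scratch/\n")
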