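#!/usr/bin/env Rscript

# Stage 5 -- mRSRF selection and survival-feature fusion.
#
# For each outcome granularity (2-, 4- and 7-category mRS), the winning
# selector extracts the mRS radiomics features (mRSRF) from the union of
# outstanding features, and a Cox partial-likelihood feed-forward network
# is trained on the training split of CTI + mRSRF with age as event time
# and poor outcome (mRS >= 3) as the event; its range-normalized risk
# score is the survival feature SurvF.

suppressMessages(library(perfrad))

seed <- 2026L
cfg <- synth_config(n_patients = 80L, n_timepoints = 50L,
                    volume_shape = c(6L, 16L, 16L), seed = seed)
coh <- generate_cohort(cfg)
sel <- readRDS("scratch/selection.rds")
bench <- readRDS("scratch/benchmark.rds")

tab <- readRDS("scratch/feature_table.rds")
outstanding <- unique(unlist(lapply(sel$fsets, `[[`, "features")))
cat("outstanding features:", length(outstanding), "\n")
lesion_m <- sel$sig$reduced[tab$row_meta$tissue == 1L, outstanding,
                            drop = FALSE]

fusion <- list()
for (s in c(2, 4, 7)) {
  skey <- sprintf("mRS_%d", s)
  labels <- regroup_mrs(coh$mrs7, s)
  mrsrf <- select_mrsrf(lesion_m, labels, bench$best_method, seed = seed)
  set.seed(seed + s)
  train_idx <- stratified_split(labels, 0.7)
  vcfg <- survival_config(epochs = 4000L, batch_size = 20L, seed = seed)
  events <- vcfg$event_rule(coh$mrs7)
  surv_x <- as.matrix(cbind(normalize_columns(coh$cti),
                            lesion_m[, mrsrf$features, drop = FALSE]))
  net <- train_survival_net(surv_x[train_idx, , drop = FALSE],
                            coh$cti$age[train_idx], events[train_idx], vcfg)
  sv <- compute_survf(net, surv_x)
  cat(sprintf("%s: %d mRSRF features, training C-index %.3f\n",
              skey, length(mrsrf$features), sv$cindex))
  utils::write.csv(data.frame(sample = seq_along(sv$survf),
                              survf = sv$survf, risk = sv$risk),
                   sprintf("results/survf_%s.csv", skey), row.names = FALSE)
  fusion[[skey]] <- list(labels = labels, mrsrf = mrsrf, survf = sv$survf,
                         cindex = sv$cindex, train_idx = train_idx)
}

# correlation of SurvF across the three situations
svm <- vapply(fusion, `[[`, numeric(80), "survf")
cat("Pearson correlations between situations' SurvF:\n")
print(round(cor(svm), 3))
saveRDS(fusion, "scratch/fusion.rds")
cat("wrote results/survf_mRS_{2,4,7}.csv\n")
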