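#!/usr/bin/env Rscript

# Stage 4 -- composite-score benchmark of the thirteen feature sets.
#
# Each method's selected features are scored by tenfold stratified
# cross-validation on the ten classifier families; the composite score CS
# is the grand mean of precision, accuracy, AUC, F1 and recall over the
# fifty (model, index) cells, and the method with the best CS becomes
# best_method for the outcome stages.

suppressMessages(library(perfrad))

seed <- 2026L
sel <- readRDS("scratch/selection.rds")

bench <- benchmark_selectors(sel$fsets, sel$sig$reduced, sel$sig$labels,
                             model_registry(), folds = 10L, seed = seed)
cs <- sort(bench$cs, decreasing = TRUE)
cat("composite scores:\n")
print(round(cs, 3))
cat("best method:", bench$best_method, "\n")

utils::write.csv(data.frame(method = names(cs), cs = as.numeric(cs)),
                 "results/composite_scores.csv", row.names = FALSE)
jsonlite::write_json(
  list(cs = as.list(bench$cs), best_method = bench$best_method,
       matrices = lapply(bench$matrices, function(m)
         as.data.frame(unclass(m)))),
  "results/benchmark_report.json", auto_unbox = TRUE, digits = NA)
saveRDS(bench, "scratch/benchmark.rds")
cat("wrote results/composite_scores.csv and results/benchmark_report.json\n")
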