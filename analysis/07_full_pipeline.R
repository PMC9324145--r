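#!/usr/bin/env Rscript

# Stage 7 -- single-command replay.
#
# Runs the orchestrated pipeline (the same computation as stages 1-6,
# driven by one configuration object) into results/pipeline_run/ and
# prints the manifest, demonstrating the deterministic one-call interface
# that the tests and the acceptance script exercise.

suppressMessages(library(perfrad))

cfg <- pipeline_config(
  seed = 2026L, outdir = "results/pipeline_run",
  synth = list(n_patients = 80L, n_timepoints = 50L,
               volume_shape = c(6L, 16L, 16L)),
  radiomics = list(enabled_classes = "First-order"),
  benchmark = list(folds = 10L),
  survival = list(epochs = 1000L),
  situations = c(2, 4, 7))

res <- run_pipeline(cfg)
cat("\nmanifest:\n")
cat(jsonlite::toJSON(res$manifest, auto_unbox = TRUE, pretty = TRUE), "\n")
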