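#!/usr/bin/env Rscript
# Stage 2: curate the active library.
#
# Standardizes the raw actives, applies the 500 Da / 500 nM strict cutoffs,
# clusters at TC 0.6 and keeps the most potent representative per cluster,
# so the training actives do not over-represent any one chemical series.

library(dualscreen)

dir <- "results/run"
cfg <- read_config(file.path(dir, "config.json"))
reps <- run_stage(cfg, "curate", dir)
man <- jsonlite::read_json(file.path(dir, "curate_manifest.json"))
cat(sprintf("curation: %d read (%d skipped) -> %d after filters -> %d cluster representatives\n",
            man$counts$read, man$counts$skipped, man$counts$after_filter,
            man$counts$representatives))
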