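#!/usr/bin/env Rscript
# Stage 5: screen the library.
#
# Scores every library molecule with the final model, keeps candidates at
# p >= 0.5 and annotates each with its nearest training active (max TC) --
# low nearest-active TC among true hits is what flags genuinely novel
# scaffolds. Also reports how the candidate list shrinks at the stricter
# p >= 0.6 used for very large libraries.

library(dualscreen)

dir <- "results/run"
cfg <- read_config(file.path(dir, "config.json"))
hits <- run_stage(cfg, "screen", dir)
truth <- read.delim(file.path(dir, "truth.tsv"))

planted <- truth$molecule_id[truth$is_active]
recall <- mean(planted %in% hits$molecule_id)
cat(sprintf("p >= %.1f candidates: %d of %d library molecules\n",
            cfg$screening$p_threshold, nrow(hits), nrow(truth)))
cat(sprintf("planted-active recall: %.0f%% (%d/%d)\n", 100 * recall,
            sum(planted %in% hits$molecule_id), length(planted)))
cat("top candidates:\n")
print(head(hits, 8), row.names = FALSE, digits = 3)

model <- readRDS(file.path(dir, "model.rds"))
lib <- read.delim(file.path(dir, "library.tsv"))
strict <- screen_library(model, lib, p_threshold = 0.6)
cat(sprintf("at p >= 0.6 the list shrinks to %d candidates\n", nrow(strict)))
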