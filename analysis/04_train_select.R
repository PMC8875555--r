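#!/usr/bin/env Rscript
# Stage 4: classifier comparison and model selection.
#
# Cross-validates the seven classifiers on the active/decoy dataset and
# selects the winner by mean MCC (ACC and AUC saturate near 1 on imbalanced
# screening data and discriminate little; MCC weighs all four confusion
# cells). The selected model is refit on all data for screening.

library(dualscreen)

dir <- "results/run"
cfg <- read_config(file.path(dir, "config.json"))
res <- run_stage(cfg, "train", dir)

tab <- read.delim(file.path(dir, "cv_metrics.tsv"))
cat("cross-validated metrics (mean over folds):\n")
print(tab[order(-tab$mcc), ], row.names = FALSE, digits = 3)
cat(sprintf("\nselected by MCC: %s (%s)\n", res$model$spec$algorithm,
            res$model$spec$fingerprint_kind))
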