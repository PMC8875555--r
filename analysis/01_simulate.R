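#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the data a screening campaign starts from: a potency-annotated
# active library sharing a benzenesulfonamide scaffold, a screening library
# with planted true actives among diverse background molecules, a decoy
# candidate pool, and dose-response / melt curves for the downstream assay
# fits. Everything is deterministic under the configured seed.

library(dualscreen)

dir <- "results/run"
cfg <- pipeline_config(
  benchmark = list(n_actives = 40L, n_background = 300L, n_planted = 15L,
                   pool_size = 1500L),
  decoys = list(n_per_active = 20L),
  training = list(algorithms = c("KNN", "NB", "Logit", "DT", "RF", "MLP",
                                 "XGBoost"), runs = 1L),
  seed = 20260926L
)
dir.create(dir, recursive = TRUE, showWarnings = FALSE)
write_config(cfg, file.path(dir, "config.json"))

bm <- run_stage(cfg, "simulate", dir)
cat(sprintf("actives: %d (potency %.0f-%.0f nM)\n", nrow(bm$actives),
            min(bm$actives$potency_nM), max(bm$actives$potency_nM)))
cat(sprintf("screening library: %d molecules, %d planted actives\n",
            nrow(bm$library), sum(startsWith(bm$library$molecule_id, "PLANT"))))

# assay inputs: three inhibitors of descending potency plus melt curves
assays <- data.frame(compound = c("CPD1", "CPD2", "CPD3"),
                     true_ic50_M = c(2.5e-7, 3.0e-7, 3.2e-5))
for (i in seq_len(nrow(assays))) {
  d <- simulate_dose_response(assays$true_ic50_M[i], hill = 1,
                              rel_noise = 0.05, seed = cfg$seed + i)
  write.table(d, file.path(dir, sprintf("dose_response_%s.tsv",
                                        assays$compound[i])),
              sep = "\t", row.names = FALSE, quote = FALSE)
}
write.table(assays, file.path(dir, "assay_truth.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

melts <- data.frame(condition = c("apo_rep1", "apo_rep2", "apo_rep3",
                                  "CPD1", "CPD2", "CPD3"),
                    true_tm = c(52.0, 52.05, 51.95, 56.5, 55.2, 52.1))
for (i in seq_len(nrow(melts))) {
  m <- simulate_melt_curve(melts$true_tm[i], slope = 2, rel_noise = 0.01,
                           seed = cfg$seed + 100 + i)
  write.table(m, file.path(dir, sprintf("melt_%s.tsv", melts$condition[i])),
              sep = "\t", row.names = FALSE, quote = FALSE)
}
write.table(melts, file.path(dir, "melt_truth.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("wrote assay tables for", nrow(assays), "compounds and",
    nrow(melts), "melt conditions\n")
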