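#!/usr/bin/env Rscript
# Stage 6: external-set validation.
#
# Emulates validating the classifier on an independent annotated set (in a
# real campaign: approved drugs with known target annotations). Any
# training active at TC >= 0.6 to an external molecule is excluded along
# with its linked decoys before retraining, so the validation cannot be
# won by memorized analogs; the retrained model then calls the external
# set at p >= 0.5.

library(dualscreen)

dir <- "results/run"
cfg <- read_config(file.path(dir, "config.json"))
actives <- read_library(file.path(dir, "actives.tsv"), "smiles-table",
                        role = "active")
pool <- read.delim(file.path(dir, "pool.tsv"))
ds <- generate_decoys(actives, pool,
                      n_per_active = cfg$decoys$n_per_active,
                      tc_active_max = cfg$decoys$tc_active_max,
                      tc_decoy_max = cfg$decoys$tc_decoy_max)

# external set: two scaffold analogs of known actives (true binders, one of
# them a near-duplicate that must trigger the exclusion) plus unrelated
# non-binders
external <- data.frame(
  molecule_id = c("EXT_ANALOG", "EXT_NOVEL", "EXT_NEG1", "EXT_NEG2",
                  "EXT_NEG3"),
  smiles = c(actives$smiles[1],
             "NS(=O)(=O)c1ccc(CCCO)cc1",
             "CC(=O)Nc1ccc(O)cc1",
             "OCC1OC(O)C(O)C(O)C1O",
             "CN1CCC(OC(=O)c2ccccc2)CC1"),
  true_binder = c(TRUE, TRUE, FALSE, FALSE, FALSE)
)
ev <- external_validation(actives, ds, external, external$true_binder,
                          spec = model_spec("Logit",
                                            cfg$training$fingerprint_kind,
                                            seed = cfg$seed),
                          tc_exclusion = cfg$external$tc_exclusion)
print(ev)
cat(sprintf("excluded training actives: %s\n",
            paste(ev$excluded_actives, collapse = ", ")))
write.table(ev$calls, file.path(dir, "external_calls.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
print(ev$calls, row.names = FALSE, digits = 3)
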