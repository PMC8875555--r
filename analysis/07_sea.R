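#!/usr/bin/env Rscript
# Stage 7: similarity-ensemble comparison.
#
# Contrasts the distribution of pairwise TCs within the training actives
# against the hits-vs-actives distribution. A cross distribution
# concentrated well below the within-class one is evidence that the
# screening hits occupy a different region of chemical space than the
# known chemotypes (scaffold novelty), even when they share the anchoring
# pharmacophore.

library(dualscreen)

dir <- "results/run"
cfg <- read_config(file.path(dir, "config.json"))
res <- run_stage(cfg, "sea", dir)

print(res$within)
if (!is.null(res$cross)) {
  print(res$cross)
  cat(sprintf("within-active median TC %.3f vs hits-vs-actives %.3f (max %.3f)\n",
              median(res$within$pair_tcs), median(res$cross$pair_tcs),
              max(res$cross$pair_tcs)))
}
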