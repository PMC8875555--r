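#!/usr/bin/env Rscript
# Stage 9: thermal-shift analysis.
#
# Fits every melt curve to the Boltzmann sigmoid inside the 40-68 deg C
# window, computes each compound's delta-Tm against the mean of the apo
# replicates, and calls a shift significant when it exceeds 3 standard
# deviations of the apo Tm replicates -- the orthogonal direct-binding
# confirmation of the enzyme-assay results.

library(dualscreen)

dir <- "results/run"
cfg <- read_config(file.path(dir, "config.json"))
truth <- read.delim(file.path(dir, "melt_truth.tsv"))

tms <- sapply(truth$condition, function(cond) {
  m <- read.delim(file.path(dir, sprintf("melt_%s.tsv", cond)))
  fit <- fit_boltzmann_tm(m$temperature_C, m$fluorescence,
                          window = cfg$dsf$window)
  stopifnot(fit$converged)
  fit$tm
})
apo <- tms[startsWith(names(tms), "apo")]
cat(sprintf("apo Tm: %.2f +- %.3f deg C (%d replicates)\n", mean(apo),
            sd(apo), length(apo)))

cpds <- names(tms)[!startsWith(names(tms), "apo")]
rows <- lapply(cpds, function(cpd) {
  call <- delta_tm_call(tms[[cpd]], apo)
  data.frame(compound = cpd, tm_C = tms[[cpd]],
             delta_tm_C = call$delta_tm, significant = call$significant)
})
tab <- do.call(rbind, rows)
write.table(tab, file.path(dir, "dsf_summary.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
print(tab, row.names = FALSE, digits = 3)
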