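#!/usr/bin/env Rscript
# Stage 4: spontaneous-IPSC unit charge under endocannabinoid-agonist
# treatment at two times of day.
#
# The wild-type profile suppresses inhibition under the agonist only at
# ZT12 (the effect is occluded at ZT0); the mutant suppresses at both
# times. Groups are compared with Kruskal-Wallis plus Dunn's post hoc.

suppressPackageStartupMessages(library(eiosc))
dir.create("results", showWarnings = FALSE)

cfg <- study_config(seed = 13, n_cells_charge = 8, stages = "charge")
res <- run_study(cfg, out_dir = "results")

cat("Unit charge (nA) by genotype, drug and ZT:\n")
print(aggregate(unit_charge ~ genotype + condition + zt, res$charge, mean))
cat("\nKruskal-Wallis per genotype:\n")
print(res$charge_stats)
cat("\nTables written to results/charge.csv and results/charge_stats.csv\n")
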