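#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study datasets.
#
# Two mouse lines are emulated against a common wild-type profile: a "flat"
# mutant whose E/I oscillation is absent, and a "reversed" mutant whose
# oscillation has inverted timing. This script writes the on-disk fixture
# bundle (sweep container, EDF, hypnogram TSV, TIFF stacks) so the later
# stages can demonstrate the full file-based workflow.

suppressPackageStartupMessages(library(eiosc))

out <- "results/datasets"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

paths <- make_fixtures(seed = 20260101, dir = out)
cat("Fixture bundle written:\n")
for (nm in names(paths)) cat(sprintf("  %-10s %s\n", nm, paths[[nm]]))

truth <- jsonlite::read_json(paths$truth)
cat(sprintf("\nGround truth: mini rate %g Hz, true ODI %.3f\n",
            truth$mini_rate_hz, truth$true_odi))
cat("States in the 1-h sleep fixture:\n")
print(unlist(truth$sleep_states))
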