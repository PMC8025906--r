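#!/usr/bin/env Rscript
# Stage 2: reduce the impactor runs to aerodynamic descriptors. Each run is
# reduced on its own (ED; probit/log-normal MMAD and GSD; fine particle mass
# from the fitted distribution over 1-5 um; FPF as percent of ED), then
# replicates are averaged per formulation (mean +/- SD, n), mirroring the
# usual summary-table presentation of cascade-impactor studies.
# Input: results/runs.csv. Output: results/aerodynamic_summary.csv.

suppressPackageStartupMessages(library(dpipk))

runs <- read_ngi_runs("results/runs.csv")
groups <- sub("_r[0-9]+$", "", vapply(runs, function(r) r$run_id, character(1)))
summary <- reduce_ngi_runs(runs, groups)
write.csv(summary, "results/aerodynamic_summary.csv", row.names = FALSE)

cat("reduced", length(runs), "runs into", nrow(summary), "formulation summaries\n")
best <- summary[which.max(summary$FPF_pct), ]
cat(sprintf("highest fine particle fraction: %s at %.1f%% (ED %.2f mg, MMAD %.2f um)\n",
            best$group, best$FPF_pct, best$ED_mg, best$MMAD_um))
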