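#!/usr/bin/env Rscript
# Simulate the four-condition adhesion study: pKO fibroblasts and their
# integrin-reconstituted lines, 10 cells per condition, contact times
# 5/20/50/120 s, one force per cell and time. Writes the tidy dataset and a
# handful of example force-distance curves.

suppressPackageStartupMessages(library(scfskit))
dir.create("results", showWarnings = FALSE)
seed <- 20260101

cfg <- simulation_config(conditions = study_conditions(), n_cells = 10,
                         seed = seed)
ds <- simulate_adhesion_dataset(cfg)
write_dataset(ds, "results/adhesion_dataset.csv")

# a few full curves (cell-scale, with noise) for the feature-extraction step
curve_cfg <- simulation_config(
  conditions = study_conditions()[c("pKO", "pKO-b1")], n_cells = 3,
  seed = seed)
cv <- simulate_dataset(curve_cfg)
dir.create("results/curves", showWarnings = FALSE)
for (cu in cv$curves)
  write_curve(cu, file.path("results/curves", paste0(cu$curve_id, ".tsv")))
write.csv(cv$truth, "results/curves_truth.csv", row.names = FALSE)

cat("Simulated", nrow(ds), "adhesion forces over",
    length(cfg$conditions), "conditions and", length(cv$curves),
    "full force-distance curves.\n")
for (cond in names(cfg$conditions)) {
  med <- median_forces(ds, cond)
  cat(sprintf("  %-10s median force: %5.2f nN (5 s) -> %5.2f nN (120 s)\n",
              cond, med[["5"]] * 1e9, med[["120"]] * 1e9))
}
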