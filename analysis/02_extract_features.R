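#!/usr/bin/env Rscript
# Read the simulated force-distance curves back from disk, baseline-correct
# them and extract the adhesion force at maximum cantilever deflection;
# compare against the generator's truth table.

suppressPackageStartupMessages(library(scfskit))

paths <- list.files("results/curves", full.names = TRUE)
stopifnot(length(paths) > 0)
curves <- lapply(paths, read_curve)
fe <- extract_features(curves)
write_features(fe, "results/curve_features.csv")

truth <- read.csv("results/curves_truth.csv")
m <- merge(fe, truth, by = "curve_id")
err <- abs(m$adhesion_force_N - m$true_adhesion_force_N)
cat(sprintf("Extracted %d curves; median |error| = %.2g pN (noise floor 10 pN)\n",
            nrow(fe), median(err) * 1e12))
cat(sprintf("Largest baseline tilt removed: %.2g nN per um of travel\n",
            max(abs(fe$baseline_slope_N_per_m)) * 1e9 / 1e6))
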