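#!/usr/bin/env Rscript
# Adhesion strengthening: average slope of the median adhesion force over
# adjacent contact times, compared between cell lines with the equal-size
# cell bootstrap + two-tailed Wilcoxon rank-sum procedure (B = 100).

suppressPackageStartupMessages(library(scfskit))
seed <- 20260104

ds <- read_dataset("results/adhesion_dataset.csv")
pairs <- list(c("pKO-aV/b1", "pKO-b1"), c("pKO-aV/b1", "pKO-aV"),
              c("pKO-b1", "pKO"))
lines <- character()
for (pr in pairs) {
  st <- slope_difference_test(ds[ds$condition == pr[1], ],
                              ds[ds$condition == pr[2], ],
                              B = 100, seed = seed)
  print(st)
  lines <- c(lines, write_report(st), "")
}
writeLines(lines, "results/slope_tests.txt")
cat("Wrote results/slope_tests.txt\n")
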