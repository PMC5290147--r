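#!/usr/bin/env Rscript
# Statistical interaction between the two integrin classes: epsilon =
# F[aV/b1] + F[pKO] - F[aV] - F[b1] per contact time, additive null
# epsilon = 0 tested on 100 cell bootstraps with a two-tailed signed-rank
# test. Negative epsilon = competition, positive = cooperation.

suppressPackageStartupMessages(library(scfskit))
seed <- 20260105

ds <- read_dataset("results/adhesion_dataset.csv")
it <- interaction_test(ds, B = 100, seed = seed)
print(it)
writeLines(write_report(it), "results/interaction_test.txt")

res <- list(epsilon_obs_nN = as.list(it$epsilon_obs * 1e9),
            p_time = as.list(it$p_time), p_pooled = it$p_pooled,
            sign = as.list(it$sign), B = it$B, seed = seed)
jsonlite::write_json(res, "results/interaction_test.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Wrote results/interaction_test.{txt,json}\n")
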