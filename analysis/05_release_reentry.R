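#!/usr/bin/env Rscript
# Release from arrest: reentry timing, the synchronous post-release HES1
# dip and its fold-change, and the coincidence of the dip with S-phase
# onset.

suppressPackageStartupMessages(library(hes1dyn))
dir.create("results", showWarnings = FALSE)

rel <- simulate_cohort("released", 100, 3, 96, 0.25, seed = 31)

re <- reentry_stats(rel, window = 30)
write.csv(re$histogram, "results/reentry_histogram.csv", row.names = FALSE)

folds <- vapply(rel$traces, release_dip_foldchange, numeric(1))
coinc <- phase_pairs(rel, "dip", "sphase_onset", tol = 1.0)
write.csv(coinc$pairs, "results/dip_sphase_pairs.csv", row.names = FALSE)

mode_bin <- re$histogram$delay_mid[which.max(re$histogram$count)]
cat(round(100 * re$fraction), "% of released cells reenter the cycle",
    "within 30 h, most commonly around", mode_bin, "h after withdrawal.\n")
cat("The post-release dip reaches a mean", round(mean(folds), 2),
    "-fold drop from the level at release, and precedes or coincides",
    "with S-phase onset (within 1 h) in",
    round(100 * coinc$a_first_or_coincident), "% of cells.\n")
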