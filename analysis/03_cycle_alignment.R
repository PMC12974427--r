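#!/usr/bin/env Rscript
# Cell cycle alignment: population averaging in real versus pseudo time
# (percent of each cell's cycle), and the timing of the HES1 dip relative
# to the final mitosis across two-generation lineages.

suppressPackageStartupMessages(library(hes1dyn))
dir.create("results", showWarnings = FALSE)

prolif <- simulate_cohort("proliferative", 90, 3, 96, 0.25, seed = 1)
rt <- population_mean(prolif, "real_time")
pt <- population_mean(prolif, "pseudo_time")
write.csv(pt, "results/pseudotime_profile.csv", row.names = FALSE)

lineage <- simulate_cohort("proliferative", 90, 3, 168, 0.25, seed = 21)
dips <- dip_timing(lineage)
write.csv(dips$dips, "results/dip_times.csv", row.names = FALSE)
write.csv(dips$density, "results/dip_time_density.csv", row.names = FALSE)

cat("Real-time averaging washes the oscillation out (peak-to-trough",
    round(diff(range(rt$mean)), 2), "z) while pseudo-synchronization",
    "reveals it (", round(diff(range(pt$mean)), 2), "z) with the minimum",
    "at", round(100 * pt$frac[which.min(pt$mean)]), "% of the cycle.\n")
cat("Across", nrow(dips$dips), "two-generation lineages the dip precedes",
    "the final mitosis by a median of",
    round(-median(dips$dips$dip_time), 1), "h (",
    dips$excluded, "boundary-minimum cells excluded).\n")
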