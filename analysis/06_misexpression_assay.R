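#!/usr/bin/env Rscript
# The 24 h release assay under inducible anti-phase HES1 misexpression:
# division fractions in the control and induced arms, and mean
# exogenous-reporter traces grouped by division fate. The companion
# unselected-culture run quantifies the 100 h division window.

suppressPackageStartupMessages(library(hes1dyn))
dir.create("results", showWarnings = FALSE)

ctrl <- simulate_cohort("released", 150, 3, 96, 0.25, seed = 41)
mis <- simulate_cohort("misexpression", 150, 3, 96, 0.25, seed = 51)
mis_tot <- filter_cohort(mis, function(tr) tr$channel == "hes1_total")

f_ctrl <- reentry_stats(ctrl, 24)$fraction
f_mis <- reentry_stats(mis_tot, 24)$fraction
write.csv(data.frame(arm = c("control", "misexpression"),
                     divided_24h = c(f_ctrl, f_mis)),
          "results/assay_division_fractions.csv", row.names = FALSE)

fate <- tet_fate_profiles(mis)
write.csv(fate, "results/tet_fate_profiles.csv", row.names = FALSE)

unsel <- simulate_cohort("proliferative", 90, 3, 120, 0.25, seed = 7,
                         snd_fraction = 0.25)
f100 <- division_fractions(unsel, 100, 1)

cat("Misexpression of anti-phase exogenous HES1 at release collapses the",
    "24 h division fraction from", round(100 * f_ctrl), "% to",
    round(100 * f_mis), "%.\n")
cat("Dividers barely induce the exogenous reporter (mean",
    round(mean(fate$divider_mean), 1), "a.u.) whereas nondividers sustain",
    round(mean(fate$nondivider_mean), 1), "a.u., keeping total HES1 from",
    "dipping below the gate.\n")
cat("In unselected proliferative cultures",
    round(100 * f100), "% of cells divide at least once within 100 h.\n")
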