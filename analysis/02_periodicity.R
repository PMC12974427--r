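#!/usr/bin/env Rscript
# Band-resolved periodicity of single-cell HES1 traces: Lomb-Scargle
# dominant periods on circadian-isolated and ultradian-isolated signals,
# ACF cross-check, and band-power contrasts against the non-oscillatory
# control reporter and the arrested regime.

suppressPackageStartupMessages(library(hes1dyn))
dir.create("results", showWarnings = FALSE)

prolif <- simulate_cohort("proliferative", 90, 3, 96, 0.25, seed = 1)
arrest <- simulate_cohort("arrested", 90, 3, 96, 0.25, seed = 11)
ctrl   <- simulate_cohort("control_nls", 90, 3, 96, 0.25, seed = 61)

circ  <- cohort_period_summary(prolif, "circadian")
ultra <- cohort_period_summary(prolif, "ultradian")
write.csv(rbind(cbind(band = "circadian", circ$histogram),
                cbind(band = "ultradian", ultra$histogram)),
          "results/period_histograms.csv", row.names = FALSE)

# ACF cross-check on the first 30 cells
acfp <- vapply(prolif$traces[1:30], function(tr)
  acf_period(isolate_band(tr, "circadian_isolated"), 40)$period_estimate,
  numeric(1))

contrasts <- do.call(rbind, lapply(
  list(c("proliferative_vs_control", "circadian"),
       c("arrested_vs_proliferative", "circadian"),
       c("arrested_vs_proliferative", "ultradian")),
  function(x) {
    pair <- if (x[1] == "proliferative_vs_control") list(prolif, ctrl)
            else list(arrest, prolif)
    bp <- band_power_compare(pair[[1]], pair[[2]], x[2])
    data.frame(contrast = x[1], band = x[2], diff = bp$diff,
               t = bp$statistic, p = bp$p.value)
  }))
write.csv(contrasts, "results/band_power_contrasts.csv", row.names = FALSE)

cat("Cycling cells oscillate with a median circadian-level period of",
    round(circ$median, 1), "h (ACF cross-check:",
    round(median(acfp, na.rm = TRUE), 1), "h) and a nested ultradian",
    "median of", round(ultra$median, 1), "h.\n")
cat("Circadian-band power: proliferative > control reporter (diff",
    signif(contrasts$diff[1], 3), ", p", signif(contrasts$p[1], 2),
    "); arrest removes it (diff", signif(contrasts$diff[2], 3),
    ") while relatively enhancing ultradian power (diff",
    signif(contrasts$diff[3], 3), ").\n")
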