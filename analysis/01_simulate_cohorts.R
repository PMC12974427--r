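#!/usr/bin/env Rscript
# Build the default synthetic cohorts for every experimental regime,
# validate them, and record their headline summary. Cohorts are fully
# reproducible from (regime, sizes, seed), so only a small example track
# table is materialized; downstream scripts regenerate cohorts in memory.

suppressPackageStartupMessages(library(hes1dyn))
dir.create("results", showWarnings = FALSE)

cohorts <- list(
  proliferative = simulate_cohort("proliferative", 90, 3, 96, 0.25, seed = 1),
  arrested      = simulate_cohort("arrested", 90, 3, 96, 0.25, seed = 11),
  released      = simulate_cohort("released", 100, 3, 96, 0.25, seed = 31),
  misexpression = simulate_cohort("misexpression", 150, 3, 96, 0.25, seed = 51),
  control_nls   = simulate_cohort("control_nls", 90, 3, 96, 0.25, seed = 61))

summ <- do.call(rbind, lapply(names(cohorts), function(nm) {
  co <- cohorts[[nm]]
  viol <- validate_cohort(co)
  stopifnot(length(viol) == 0)
  data.frame(regime = nm, traces = length(co),
             duration_h = co$duration, dt_h = co$dt,
             mean_intensity = mean(unlist(lapply(co$traces,
                                                 function(tr) mean(tr$values)))),
             mitoses = sum(vapply(co$traces,
                                  function(tr) length(tr$mitosis_times),
                                  numeric(1))))
}))
write.csv(summ, "results/cohort_summary.csv", row.names = FALSE)

# compact standalone example of the exchange format
demo <- simulate_cohort("released", 3, 1, 48, 0.5, seed = 31)
write_tracks(demo, "results/example_tracks.csv")

cat("Simulated", sum(summ$traces), "traces across", nrow(summ),
    "regimes; all cohorts pass validation.\n")
cat("Arrested cells sit at",
    round(summ$mean_intensity[summ$regime == "arrested"] /
            summ$mean_intensity[summ$regime == "proliferative"], 2),
    "x the proliferative mean level, as expected during arrest.\n")
print(summ, row.names = FALSE)
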