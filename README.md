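# hes1dyn

Quantification pipeline for single-cell HES1 protein oscillations across
proliferation, reversible cell cycle arrest and reentry in ER+ breast
cancer cells, with a calibrated synthetic cohort generator that emulates
each experimental regime.

## The problem

HES1, a Notch-pathway transcriptional repressor, oscillates at the protein
level in single cells. In cycling MCF-7 cells the dominant oscillation is
*circadian-level* (~24 h, the 20–30 h band) and phase-locked to the cell
cycle: expression is high after mitosis, declines to a transient minimum —
the **dip** — 10–14 h before the next mitosis at the G1/S transition, and
rises again before division. A weaker nested **ultradian** component
(4–8 h band, median period 6–7 h) rides on top. During CDK4/6-inhibitor
(palbociclib) arrest the cycle-locked oscillation disappears and mean
HES1 rises ~1.4-fold (the baseline rises ~1.6-fold, the peak only
~1.1-fold); on release, cells reenter the cycle synchronously, HES1 shows
a deep dip (mean 2.2-fold) that precedes or coincides with S-phase entry
in ~89% of cells, and forcing anti-phase exogenous HES1 at release — which
flattens total HES1 — collapses the 24 h reentry fraction from ~75% to
~14%. These are the quantities this package computes, end to end.

For a trace $x(t)$ sampled at step $\Delta t$, the pipeline detrends by
centered moving-average subtraction (window $W$; residual amplitude of a
period-$T$ sinusoid is $1-\mathrm{sinc}(W/T)$, with $W=40$ h isolating
circadian-level and $W=12$ h isolating ultradian content), estimates
periodicity with a floating-mean Lomb–Scargle periodogram normalized so
power = variance fraction explained at each frequency (with an
autocorrelation pipeline as cross-check), pseudo-synchronizes
mitosis-to-mitosis segments onto percent-of-cycle, and derives event
statistics: dip timing relative to mitosis, peak–dip amplitudes,
release-dip fold-changes, dip/S-phase phase relations (coincident within
1 h), reentry fractions and division fractions.

Because the raw imaging data are external, the package ships a
first-class synthetic generator (`simulate_cohort()`) whose five regimes
— `proliferative`, `arrested`, `released`, `misexpression`,
`control_nls` — are calibrated to the printed statistics above (see the
methods vignette in `vignettes/` for the model and calibration).

## Worked example

```r
library(hes1dyn)

# A released-regime cohort: 3 replicates x 100 cells, 96 h at 15 min
cohort <- simulate_cohort("released", n_cells = 100, n_replicates = 3,
                          duration = 96, dt = 0.25, seed = 31)
cohort
#> <hes_cohort> 300 traces, dt = 0.25 h, duration = 96 h

reentry <- reentry_stats(cohort, window = 30)
round(reentry$fraction, 3)
#> [1] 0.85

folds <- vapply(cohort$traces, release_dip_foldchange, numeric(1))
round(mean(folds), 2)
#> [1] 2.25

coinc <- phase_pairs(cohort, "dip", "sphase_onset", tol = 1)
round(coinc$a_first_or_coincident, 3)
#> [1] 0.903

prolif <- simulate_cohort("proliferative", 90, 3, 96, 0.25, seed = 1)
summary_circ <- cohort_period_summary(prolif, "circadian")
round(summary_circ$median, 1)
#> [1] 24
```

Reading the output: 85% of released cells show a mitosis within 30 h of
drug withdrawal; the post-release HES1 dip is a mean 2.25-fold drop from
the level at release; it precedes or coincides (within 1 h) with the
annotated S-phase onset in 90% of cells; and the cycling cohort's median
circadian-level Lomb–Scargle period is 24 h.

## The analysis workflow

The study runs as numbered drivers over the package functions, each
writing its tables under `results/`:

| script | step |
|---|---|
| `analysis/01_simulate_cohorts.R` | build and validate all regime cohorts |
| `analysis/02_periodicity.R` | LSP/ACF period medians, band-power contrasts |
| `analysis/03_cycle_alignment.R` | real- vs pseudo-time averaging, dip timing |
| `analysis/04_arrest_levels.R` | arrest intensity fold-changes, amplitudes |
| `analysis/05_release_reentry.R` | reentry timing, dip fold-change, S-phase coincidence |
| `analysis/06_misexpression_assay.R` | 24 h release assay, divider/nondivider profiles |

`run_report()` performs the whole sequence in one call and tabulates the
twelve headline quantities with pass/fail against their expected ranges.

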