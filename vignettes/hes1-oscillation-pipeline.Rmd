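---
title: "Quantifying cell cycle-locked HES1 oscillations, arrest and reentry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell cycle-locked HES1 oscillations, arrest and reentry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hes1dyn)
```

## The biological setting and what the pipeline measures

HES1 is a Notch-pathway transcriptional repressor whose protein level
oscillates in single cells. In cycling ER+ breast cancer cells the dominant
oscillation has a circa-24 h period locked to cell cycle progression — high
after mitosis, transiently declining to a minimum (the *dip*) 10–14 h before
the next mitosis, around the G1/S transition — with a weaker nested
ultradian (4–8 h) component attributed to HES1 autorepression. During
reversible CDK4/6-inhibitor arrest the cycle-locked component disappears,
mean levels rise ~1.4-fold (the baseline rises, not the peak), and ultradian
fluctuations become relatively more prominent. Upon drug withdrawal cells
reenter the cycle largely synchronously, a deep HES1 dip precedes S-phase
entry, and misexpressing exogenous HES1 in anti-phase — which flattens the
total HES1 profile — blocks reentry.

`hes1dyn` implements the complete quantification pipeline for such data:
long-format track IO and validation; z-scoring and band-isolating
detrending; Lomb–Scargle (LSP) and autocorrelation (ACF) periodicity with
band-power statistics; mitosis-to-mitosis pseudo-time alignment and
dip-timing; event detection, phase relations, reentry, division-fraction
and intensity-level statistics; plus a calibrated synthetic cohort
generator so that every quantification can be exercised, end to end,
without the original imaging data. The numbered scripts under `analysis/`
run the full study as a sequence of narrated steps.

## The synthetic cohort model

Each cell is simulated at `dt = 0.25` h (chosen so a 4 h ultradian period
is resolved by 16 samples per cycle; time is in hours, intensity in linear
arbitrary units throughout).

**Proliferative regime.** Cycle lengths are lognormal with median 23.3 h
(sdlog 0.15). Within a cycle of length $T$ with dip lead $L \sim
U[10, 14]$ h, the cycle-locked component is a single raised cosine
$w(u) = -\cos\!\big(2\pi(u - u_\mathrm{dip})\big)$ on cycle fraction
$u \in [0,1]$ with $u_\mathrm{dip} = 1 - L/T$, so the minimum falls $L$
hours before the next mitosis and the maxima sit near both mitoses. The
observed waveform is biphasic (peak–dip–peak); a raised cosine is the
simplest smooth shape with that structure, and its closed form gives the
test suite exact oracles. The signal is

$$x(t) = B\big(1 + A_{cc}\, w(u) + A_u \sin(2\pi t/T_u + \varphi)\big)
  + \mathrm{OU}(t) + \varepsilon_t$$

with baseline $B = 100$ a.u., cycle amplitude $A_{cc} = 0.45$, ultradian
amplitude $A_u = 0.06$, per-cell ultradian period $T_u \sim U[5.5, 7.5]$ h
and phase $\varphi \sim U[0, 2\pi)$ — phases are independent across cells,
which is what makes real-time population averages flat while pseudo-time
averages are not. Noise has two parts: white measurement noise
(sd 1.5 a.u., ~1.5% of baseline, typical for nuclear fluorescence
quantification) and an Ornstein–Uhlenbeck process (sd 2 a.u., correlation
time 3 h) standing in for slow biological variability. S-phase onsets are
annotated at the per-cycle dip time plus $N(1.0, 1.6^2)$ h.

The default proliferative regime represents the mitosis-tracked cycling
cohort used for the oscillation analyses. Unselected cultures additionally
contain spontaneously nondividing cells; setting `snd_fraction = 0.25`
adds that subpopulation (arrested-like signal, no mitoses), which is how
the 100 h division-window assay is emulated (~75% of cells divide at
least once).

**Arrested regime.** No mitoses. The level is $1.4 B$ and the fluctuation
is the ultradian sinusoid ($A_u = 0.14$) plus a mean-compensated periodic
train of downward dips (depth 0.36 relative, width 2.5 h) at the sinusoid
minima. The dip train is what reconciles three observed level statistics
simultaneously: mean up 1.4-fold, maximum up only ~1.1-fold, minimum up
~1.6-fold — a symmetric sinusoid alone cannot produce that asymmetry — and
it matches the observation that arrest enhances ultradian dip amplitudes
while keeping them below the G1/S dips of cycling cells. The depth
constant was fixed once by simulation search against those level ratios
(see *Calibration*).

**Released regime.** Arrested signal until the release time (default 2 h
into the recording), then a deterministic curve: a slowly drifting
envelope from the value at release toward the pre-mitotic peak, minus a
localized raised-cosine dip (width up to 10 h) whose bottom equals the
value at release divided by 2.2, at a per-cell dip time $U[8, 10]$ h
post release. The localized shape keeps realistic curvature at the
minimum; an earlier construction with end-to-end half-cosines had a
nearly flat bottom on which slow noise displaced the detected minimum by
about an hour. The ultradian term is omitted between release and the
first mitosis, consistent with the observed drop in ultradian power on
release. S-phase onset is the dip time plus $N(1.0, 1.6^2)$ h; with the
1 h coincidence tolerance the generative law implies a
dip-before-or-at-S-phase fraction of $\Phi(2/1.6) \approx 0.894$, the
closed-form oracle used in testing.

Reentry timing (first mitosis after release) is a two-component mixture:
a synchronous wave, 72% of cells at $N(18.5, 2.5^2)$ h (truncated at
13 h), plus a straggler tail, 28% lognormal with median 30.5 h
(sdlog 0.23). A single lognormal cannot jointly produce the three
reported statistics — a modal reentry time of ~18–19 h, ~75% of cells
divided by 24 h and ~85% by 30 h — whereas the mixture satisfies all
three in closed form (F(24) = 0.75, F(30) = 0.85, mode 18.5 h) and
reflects the described biology: a synchronous reentry wave whose
synchrony is quickly lost. After the first mitosis, cells continue with
the proliferative waveform.

**Misexpression regime.** The endogenous channel follows the released
construction; an exogenous channel is induced at release and rises in
anti-phase to the endogenous dip, with per-cell peak amplitude lognormal
(median 36 a.u., sdlog 0.8) reflecting heterogeneous induction; the total
channel is their sum. Division is gated mechanistically, not by a
coin flip: a cell divides only if its total trace falls below
$\theta = 0.55$ of its value at release within 15 h. Control cells
(no exogenous channel) dip to $1/2.2 \approx 0.45$ of release and always
pass; induced cells pass only when induction is weak, because the
exogenous protein fills the dip. Nondividers keep the endogenous channel
repressed in proportion to the sustained exogenous level, so their total
profile is flat and total-channel variance falls below the
endogenous-alone variance, as seen in dual-reporter data. The gate
threshold and amplitude distribution were calibrated once against the
24 h-assay division fractions (~75% control, ~14% induced).

**Control reporter regime.** Constant baseline plus a mild linear drift
(0.05 a.u./h) and the same noise — no periodic terms.

### What the generator does not emulate

Cell death and viability (the real assay excludes dying cells from the
24 h denominator; the synthetic denominator is all cells), serum-response
transients after media change, mechanistic delay-differential HES1
autorepression, Notch-mediated coupling between neighbours, lineage
structure beyond a single track, track censoring by cells leaving the
field (hence the "50% divide twice in 100 h" companion statistic is not
reproduced), and imaging artifacts (background, bleaching,
segmentation noise beyond the white + OU model). Passing tests therefore
demonstrate that the *analysis* recovers the statistics a cohort with this
generative structure carries — not that real imaging data are this clean.

## Analysis methods and numerical choices

**Detrending** subtracts a centered moving average; edge windows truncate
symmetrically, so a linear ramp detrends to zero everywhere. A window of
width $W$ attenuates a period-$T$ sinusoid by $\mathrm{sinc}(W/T)$, so the
residual retains $1 - \mathrm{sinc}(W/T)$ of its amplitude — a closed-form
oracle the tests exploit. The 40 h window (*circadian_isolated*) removes
only slow drift; the 12 h window (*ultradian_isolated*) also removes the
circadian-level component (24 h retention ≈ 0.38, 6 h retention ≈ 0.98).
Moving-average subtraction was chosen over wavelet or Gaussian-process
detrending for linearity and exact testability; both windows are exposed
in `analysis_config()`. Z-scoring uses the population standard deviation
and maps constant traces to zeros so degenerate channels flow through;
detrending happens on raw intensities, with z-scoring applied afterwards
for display and aggregation only.

**Lomb–Scargle periodogram.** Implemented in the floating-mean
(generalized) least-squares form with "standard" normalization: power at
a frequency is the fraction of trace variance explained by the
least-squares sine+cosine fit there, hence lies in [0, 1] and is
comparable across traces and invariant to affine intensity transforms.
The grid spans the search range at four times the natural resolution
$1/\mathrm{span}$. Dominant-period search ranges are 15–35 h
(circadian-level) and 3–10 h (ultradian); power-band summaries use the
20–30 h and 4–8 h bands. Ties at maximum power break toward the longer
period, which stabilizes near-flat spectra. The test suite checks the
implementation against an independent per-frequency `lm()` oracle to
1e-6.

**ACF.** Biased-normalized autocorrelation (`stats::acf`); the period
estimate is the lag of the first local maximum after the first zero
crossing, reported only when it exceeds $2/\sqrt{N}$ — no significance
rule is inherited from elsewhere, so this conventional threshold is made
explicit.

**Band-power comparison.** For each cohort, mean normalized power at each
in-band grid frequency, pooling cells within replicate and then averaging
replicates; the two sets of per-frequency means are compared with a Welch
two-sample t test, mirroring how such figures report "mean power at a
given frequency". No multiple-testing correction is applied because a
single band is tested per contrast.

**Alignment.** Pseudo-time warping linearly interpolates each
mitosis-to-mitosis segment onto 101 points (0–100% of the cycle; the bin
count is a display resolution, results are insensitive to it). Dip timing
uses the last three annotated mitoses per cell, circadian-isolated and
z-scored, and takes the interior minimum of the daughter generation;
minima on segment boundaries are excluded as mitotic-signal artifacts.
Segments with cycle lengths outside 6–80 h are flagged but kept.

**Events.** Extrema are detected by topographic prominence with
alternation enforced; the default threshold is 0.5 z-units, expressed on
a band-isolated trace's own scale as 0.5 times its standard deviation.
Prominence ties break toward earlier time. The post-release dip is
located as the minimum of the lightly smoothed (1.5 h) trace within 15 h
of release. The release fold-change divides the value at release by the
window minimum (release sample included, so the fold is ≥ 1; the window
ends at the first mitosis, or at 15 h for non-dividers). Event times are
real-valued hours; snapping to samples happens only inside operations
that need indices, with ties toward the earlier sample.

## Calibration

Constants with printed anchors are taken directly: cycle median 23.3 h,
dip lead 10–14 h, arrest level factor 1.4, release-dip fold 2.2, bands
20–30 h and 4–8 h, coincidence tolerance 1 h. Free constants — the arrest
dip-train depth, the exogenous amplitude distribution and the gate
threshold — were fixed once by a small simulation search (seeds 1–5)
against the level ratios (max ~1.1-fold, min ~1.6-fold), the 24 h-assay
fractions (~75% / ~14%) and the dip–S-phase fraction (~89%), and then
frozen in `regime_params()`; they are never adjusted at analysis time.

## Problem sizes and reproducibility

The shipped end-to-end report (`run_report()`, also driven by
`scripts/acceptance.R`) uses 3 replicates of 90 cells at 96 h for the
proliferative, arrested and control cohorts, 90 cells at 168 h for the
two-generation lineage cohort, 100 cells for the released cohort and 150
cells per arm for the 24 h assay — comparable to the imaging study's
n = 90–115 per condition — and completes in a few seconds. All randomness
flows from a single integer seed; identical seeds yield byte-identical
cohorts and identical report tables. Unit tests use smaller cohorts where
a direction or invariance, rather than a calibrated magnitude, is under
test.

## Known limitations

The LSP period grid is coarse near 24 h for 96 h recordings
(≈1.4 h spacing at fourfold oversampling), so cohort medians snap to grid
values; the dominant-period histogram should be read with that
granularity in mind. The ACF period rule returns no estimate for heavily
damped oscillations even when the LSP still ranks the band highly. The
misexpression gate is deterministic given the trace, so assay fractions
inherit the variability of the induction distribution only. Missing
samples and non-uniform sampling are rejected rather than interpolated —
gap handling is deliberately out of scope.
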