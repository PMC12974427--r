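## Periodicity estimation: Lomb-Scargle periodogram (LSP) and
## autocorrelation (ACF) pipelines, plus cohort-level band-power
## statistics.
##
## The LSP uses the floating-mean (generalized) least-squares formulation
## with "standard" normalization: the power at a frequency is the fraction
## of trace variance explained by the least-squares sine+cosine fit at
## that frequency, so powers lie in [0, 1] and are comparable across
## traces.

#' Lomb-Scargle periodogram of a trace
#'
#' Evaluates normalized power on a frequency grid from `1/period_max` to
#' `1/period_min` with `oversampling` times the natural resolution
#' `1/span`. The dominant period is the grid period of maximum power; ties
#' break toward the longer period.
#'
#' @param trace An `hes_trace` (raw or detrended).
#' @param period_min,period_max Period search range in hours;
#'   `period_max` must not exceed half the trace span.
#' @param oversampling Frequency-grid oversampling factor (default 4).
#' @return A list of class `hes_spectrum` with `period_grid` (ascending
#'   periods, i.e. descending frequency), `power`, `dominant_period` and
#'   the trace identity.
#' @export
lomb_scargle <- function(trace, period_min, period_max, oversampling = 4) {
  t <- trace$times; x <- trace$values
  n <- length(t)
  if (n < 16) stop("range error: need at least 16 samples")
  span <- max(t) - min(t)
  if (span < 2 * period_min)
    stop("range error: trace shorter than twice period_min")
  if (period_max > span / 2)
    stop("range error: period_max exceeds half the trace span")
  df <- 1 / (span * oversampling)
  freqs <- seq(1 / period_max, 1 / period_min, by = df)
  freqs <- sort(freqs, decreasing = TRUE)      # periods ascending
  power <- ls_power(t, x, freqs)
  periods <- 1 / freqs
  best <- which(power == max(power))
  dominant <- max(periods[best])               # tie toward longer period
  structure(list(cell_id = trace$cell_id, replicate_id = trace$replicate_id,
                 band_label = trace$band_label %||% "raw",
                 period_grid = periods, power = power,
                 dominant_period = dominant),
            class = "hes_spectrum")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Variance fraction explained by a least-squares fit
## y ~ 1 + cos(2*pi*f*t) + sin(2*pi*f*t), per frequency (vectorized).
ls_power <- function(t, x, freqs) {
  n <- length(t)
  y <- x - mean(x)
  yy <- sum(y^2)
  if (yy <= 0) return(rep(0, length(freqs)))
  wt <- outer(t, 2 * pi * freqs)               # n x nf phase matrix
  co <- cos(wt); si <- sin(wt)
  mc <- colMeans(co); ms <- colMeans(si)
  cc <- colSums(co * co) - n * mc^2
  ss <- colSums(si * si) - n * ms^2
  cs <- colSums(co * si) - n * mc * ms
  yc <- colSums(y * co)
  ys <- colSums(y * si)
  d <- cc * ss - cs^2
  p <- (ss * yc^2 + cc * ys^2 - 2 * cs * yc * ys) / (d * yy)
  pmin(pmax(p, 0), 1)
}

#' Mean normalized power inside a period band
#'
#' @param spectrum An `hes_spectrum`.
#' @param band `c(low, high)` period band in hours.
#' @return Mean power over grid points whose period lies in the band.
#' @export
band_power <- function(spectrum, band) {
  sel <- spectrum$period_grid >= band[1] & spectrum$period_grid <= band[2]
  if (!any(sel)) return(NA_real_)
  mean(spectrum$power[sel])
}

#' Autocorrelation-based period estimate
#'
#' Biased-normalized autocorrelation; the period estimate is the lag of
#' the first local maximum after the first zero crossing, reported only
#' when that maximum exceeds the significance level `2/sqrt(N)`.
#'
#' @param trace An `hes_trace` (raw or detrended).
#' @param max_lag Maximum lag in hours; at most half the trace span.
#' @return A list of class `hes_acf` with `lags`, `acf` and
#'   `period_estimate` (`NA` when no significant peak exists).
#' @export
acf_period <- function(trace, max_lag) {
  span <- max(trace$times) - min(trace$times)
  if (max_lag > span / 2)
    stop("range error: max_lag exceeds half the trace span")
  nlag <- as.integer(round(max_lag / trace$dt))
  r <- as.numeric(stats::acf(trace$values, lag.max = nlag, plot = FALSE,
                             demean = TRUE)$acf)
  lags <- seq(0, nlag) * trace$dt
  period <- NA_real_
  zc <- which(r <= 0)[1]
  if (!is.na(zc) && zc < length(r) - 1) {
    i <- seq(max(zc + 1, 2), length(r) - 1)
    locmax <- i[r[i] > r[i - 1] & r[i] >= r[i + 1]]
    thr <- 2 / sqrt(length(trace$values))
    if (length(locmax) && r[locmax[1]] > thr) period <- lags[locmax[1]]
  }
  structure(list(cell_id = trace$cell_id, lags = lags, acf = r,
                 period_estimate = period),
            class = "hes_acf")
}

## Band label -> detrending window + period search range used for
## dominant-period extraction.
band_setup <- function(band_label, config) {
  if (band_label == "circadian")
    list(iso = "circadian_isolated", search = c(15, 35),
         band = config$circadian_band)
  else
    list(iso = "ultradian_isolated", search = c(3, 10),
         band = config$ultradian_band)
}

#' Cohort-level dominant-period summary
#'
#' Band-isolates every HES1 trace, extracts the per-cell dominant LSP
#' period in the band's search range (15-35 h circadian-level, 3-10 h
#' ultradian) and pools cells across replicates.
#'
#' @param cohort A [new_cohort()] object.
#' @param band_label `"circadian"` or `"ultradian"`.
#' @param config An [analysis_config()].
#' @param oversampling LSP grid oversampling.
#' @return A list with per-cell `periods` (data frame), the pooled
#'   `median` and a 1 h-bin `histogram`.
#' @export
cohort_period_summary <- function(cohort,
                                  band_label = c("circadian", "ultradian"),
                                  config = analysis_config(),
                                  oversampling = 4) {
  band_label <- match.arg(band_label)
  if (!length(cohort$traces)) stop("empty cohort")
  bs <- band_setup(band_label, config)
  rows <- lapply(cohort$traces, function(tr) {
    d <- isolate_band(tr, bs$iso, config)
    sp <- lomb_scargle(d, bs$search[1], bs$search[2], oversampling)
    data.frame(replicate_id = tr$replicate_id, cell_id = tr$cell_id,
               dominant_period = sp$dominant_period,
               stringsAsFactors = FALSE)
  })
  periods <- do.call(rbind, rows)
  med <- stats::median(periods$dominant_period)
  breaks <- seq(floor(bs$search[1]), ceiling(bs$search[2]), by = 1)
  h <- graphics::hist(periods$dominant_period, breaks = breaks, plot = FALSE)
  list(periods = periods, median = med,
       histogram = data.frame(period_mid = h$mids, count = h$counts))
}

## Per-frequency mean power for one cohort: cells pooled within replicate,
## then replicates averaged.
cohort_band_spectrum <- function(cohort, band_label, config, oversampling) {
  bs <- band_setup(band_label, config)
  specs <- lapply(cohort$traces, function(tr) {
    d <- isolate_band(tr, bs$iso, config)
    lomb_scargle(d, bs$band[1], bs$band[2], oversampling)
  })
  grid <- specs[[1]]$period_grid
  for (sp in specs)
    if (length(sp$period_grid) != length(grid) ||
        max(abs(sp$period_grid - grid)) > 1e-9)
      stop("comparison error: traces analyzed on different grids")
  pw <- do.call(rbind, lapply(specs, function(sp) sp$power))
  reps <- vapply(cohort$traces, function(tr) tr$replicate_id, character(1))
  per_rep <- rowsum(pw, reps) / as.vector(table(reps)[sort(unique(reps))])
  list(period_grid = grid, mean_power = colMeans(per_rep))
}

#' Compare oscillation band power between two cohorts
#'
#' For each cohort, computes the mean normalized LSP power at each
#' in-band grid frequency (cells pooled within replicate, replicates
#' averaged) and contrasts the two sets of per-frequency means with a
#' Welch two-sample t test - the unit of comparison being "mean power at a
#' given frequency".
#'
#' @param cohort_a,cohort_b Cohorts sampled on identical grids.
#' @param band_label `"circadian"` or `"ultradian"`.
#' @param config An [analysis_config()].
#' @param oversampling LSP grid oversampling.
#' @return A list with the shared `period_grid`, per-frequency means for
#'   both cohorts, the group mean difference `diff` (a minus b) and the
#'   Welch `statistic` and `p.value`.
#' @export
band_power_compare <- function(cohort_a, cohort_b,
                               band_label = c("circadian", "ultradian"),
                               config = analysis_config(),
                               oversampling = 4) {
  band_label <- match.arg(band_label)
  if (is.na(cohort_a$dt) || is.na(cohort_b$dt) ||
      abs(cohort_a$dt - cohort_b$dt) > 1e-9 ||
      abs(cohort_a$duration - cohort_b$duration) > 1e-9)
    stop("comparison error: cohorts sampled on different grids")
  a <- cohort_band_spectrum(cohort_a, band_label, config, oversampling)
  b <- cohort_band_spectrum(cohort_b, band_label, config, oversampling)
  tt <- stats::t.test(a$mean_power, b$mean_power)
  list(period_grid = a$period_grid,
       mean_power_a = a$mean_power, mean_power_b = b$mean_power,
       diff = mean(a$mean_power) - mean(b$mean_power),
       statistic = unname(tt$statistic), p.value = tt$p.value)
}
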