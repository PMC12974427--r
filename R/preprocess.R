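## Normalization and band-isolating detrending.
##
## Detrending subtracts a centered moving average; subtracting a long
## (40 h) window leaves circadian-level and faster components
## ("circadian_isolated"), a short (12 h) window leaves only ultradian
## components ("ultradian_isolated"). The moving average of width W
## attenuates a sinusoid of period T by sinc(W/T) = sin(pi*W/T)/(pi*W/T),
## so the detrended residual keeps 1 - sinc(W/T) of its amplitude - the
## closed form used by the test oracles.

#' Z-score normalize a trace
#'
#' Centers to mean 0 and scales to population standard deviation 1
#' (divisor n). Constant traces map to all zeros so degenerate control
#' channels flow through the pipeline.
#'
#' @param trace An `hes_trace` (annotations are preserved).
#' @return The z-scored trace.
#' @export
zscore_trace <- function(trace) {
  x <- trace$values
  if (length(x) < 2) stop("length error: z-score needs >= 2 samples")
  s <- stats::sd(x) * sqrt((length(x) - 1) / length(x))
  trace$values <- if (s > 0) (x - mean(x)) / s else rep(0, length(x))
  trace
}

## Centered moving average with edge windows truncated symmetrically to
## the available span, so a linear ramp is reproduced exactly everywhere.
moving_average <- function(x, k) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  ki <- pmin(k, i - 1L, n - i)
  (cs[i + ki + 1L] - cs[i - ki]) / (2 * ki + 1)
}

#' Subtract a centered moving average from a trace
#'
#' @param trace An `hes_trace`.
#' @param window Moving-average width in hours; must be at least `3 * dt`
#'   and shorter than the trace span.
#' @return A trace of class `c("hes_detrended", "hes_trace")` carrying
#'   `band_label` and `window_used` fields; sampling unchanged.
#' @export
detrend_trace <- function(trace, window) {
  dt <- trace$dt
  span <- max(trace$times) - min(trace$times)
  if (window < 3 * dt)
    stop("parameter error: window must be at least 3*dt")
  if (span <= window)
    stop("parameter error: trace (", span, " h) not longer than window")
  k <- max(1L, as.integer(floor(window / (2 * dt))))
  trace$values <- trace$values - moving_average(trace$values, k)
  trace$band_label <- "raw"
  trace$window_used <- (2 * k + 1) * dt
  class(trace) <- unique(c("hes_detrended", class(trace)))
  trace
}

#' Isolate the circadian-level or ultradian band of a trace
#'
#' `"circadian_isolated"` removes drift slower than the circadian band by
#' subtracting a long moving average (default 40 h);
#' `"ultradian_isolated"` additionally removes circadian-level components
#' with a short window (default 12 h).
#'
#' @param trace An `hes_trace`.
#' @param band_label `"circadian_isolated"` or `"ultradian_isolated"`.
#' @param config An [analysis_config()] supplying the window defaults.
#' @return A detrended trace labelled with the band.
#' @export
isolate_band <- function(trace,
                         band_label = c("circadian_isolated",
                                        "ultradian_isolated"),
                         config = analysis_config()) {
  band_label <- match.arg(band_label)
  window <- if (band_label == "circadian_isolated")
    config$detrend_window_long else config$detrend_window_short
  out <- detrend_trace(trace, window)
  out$band_label <- band_label
  out
}

## Apply a per-trace transformation across a cohort.
map_cohort <- function(cohort, f, ...) {
  cohort$traces <- lapply(cohort$traces, f, ...)
  cohort
}
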