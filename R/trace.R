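#' @keywords internal
"_PACKAGE"

## Core data containers: a Trace is one cell x one channel uniformly sampled
## intensity series with event annotations; a Cohort is a set of Traces
## sharing sampling and condition/replicate metadata.

TRACE_CONDITIONS <- c("proliferative", "arrested", "released",
                      "misexpression", "control_nls")
TRACE_CHANNELS   <- c("hes1_endo", "hes1_exo", "hes1_total",
                      "cdk2", "p21", "control")
TIME_TOL <- 1e-9

#' Construct a single-cell trace
#'
#' A trace holds one cell's uniformly sampled fluorescence intensity on one
#' channel (hours / arbitrary units), plus ground-truth or annotated event
#' times: mitoses, S-phase onsets and (for release experiments) the time of
#' drug withdrawal.
#'
#' @param cell_id,replicate_id Character identifiers.
#' @param condition One of `"proliferative"`, `"arrested"`, `"released"`,
#'   `"misexpression"`, `"control_nls"`.
#' @param channel One of `"hes1_endo"`, `"hes1_exo"`, `"hes1_total"`,
#'   `"cdk2"`, `"p21"`, `"control"`.
#' @param times Strictly increasing sample times in hours with a constant
#'   step (tolerance 1e-9 h).
#' @param values Intensities, same length as `times`.
#' @param mitosis_times,sphase_times Sorted event times in hours (may be
#'   empty).
#' @param release_time Release time in hours, or `NA` if not applicable.
#' @return An object of class `hes_trace`.
#' @export
new_trace <- function(cell_id, replicate_id, condition, channel,
                      times, values,
                      mitosis_times = numeric(0),
                      sphase_times = numeric(0),
                      release_time = NA_real_) {
  condition <- match.arg(condition, TRACE_CONDITIONS)
  channel <- match.arg(channel, TRACE_CHANNELS)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) < 2) stop("a trace needs at least 2 samples")
  dt <- trace_step(times)
  structure(
    list(cell_id = as.character(cell_id),
         replicate_id = as.character(replicate_id),
         condition = condition, channel = channel,
         times = times, values = values, dt = dt,
         mitosis_times = sort(as.numeric(mitosis_times)),
         sphase_times = sort(as.numeric(sphase_times)),
         release_time = as.numeric(release_time)[1]),
    class = "hes_trace")
}

## Constant sampling step, or error when the grid is not uniform.
trace_step <- function(times) {
  d <- diff(times)
  if (any(d <= 0)) stop("sampling error: times must be strictly increasing")
  if (max(d) - min(d) > TIME_TOL)
    stop("sampling error: non-uniform time step (tolerance 1e-9 h)")
  mean(d)
}

#' Construct a cohort of traces
#'
#' @param traces List of [new_trace()] objects sharing the sampling step.
#' @param provenance Free-form list recording generator parameters, seed and
#'   software version.
#' @return An object of class `hes_cohort`.
#' @export
new_cohort <- function(traces = list(), provenance = list()) {
  if (length(traces)) {
    stopifnot(all(vapply(traces, inherits, logical(1), "hes_trace")))
    dts <- vapply(traces, function(tr) tr$dt, numeric(1))
    if (max(dts) - min(dts) > TIME_TOL)
      stop("all traces in a cohort must share dt")
    dt <- dts[[1]]
    duration <- max(vapply(traces, function(tr) max(tr$times) - min(tr$times),
                           numeric(1)))
  } else {
    dt <- NA_real_
    duration <- NA_real_
  }
  structure(list(traces = traces, dt = dt, duration = duration,
                 provenance = provenance),
            class = "hes_cohort")
}

#' @export
print.hes_trace <- function(x, ...) {
  cat(sprintf("<hes_trace> %s/%s [%s, %s] %d samples, dt = %g h\n",
              x$replicate_id, x$cell_id, x$condition, x$channel,
              length(x$times), x$dt))
  cat(sprintf("  span %g-%g h | %d mitoses | %d S-phase onsets | release %s\n",
              min(x$times), max(x$times), length(x$mitosis_times),
              length(x$sphase_times),
              ifelse(is.na(x$release_time), "-",
                     format(x$release_time))))
  invisible(x)
}

#' @export
print.hes_cohort <- function(x, ...) {
  cat(sprintf("<hes_cohort> %d traces, dt = %s h, duration = %s h\n",
              length(x$traces),
              format(x$dt), format(x$duration)))
  invisible(x)
}

#' @export
length.hes_cohort <- function(x) length(x$traces)

#' Subset a cohort by a predicate on traces
#'
#' @param cohort A [new_cohort()] object.
#' @param keep Logical vector or a function `trace -> logical`.
#' @return The filtered cohort (provenance preserved).
#' @export
filter_cohort <- function(cohort, keep) {
  if (is.function(keep))
    keep <- vapply(cohort$traces, keep, logical(1))
  new_cohort(cohort$traces[keep], cohort$provenance)
}

#' Report invariant violations in a cohort
#'
#' Checks every trace against the container invariants (uniform strictly
#' increasing times, equal lengths, finite non-negative raw intensities,
#' event times inside the sampled span) and returns a character vector of
#' violations, each naming the offending trace and rule. It never throws:
#' a well-formed cohort yields `character(0)`.
#'
#' @param cohort A [new_cohort()] object.
#' @return Character vector of violation descriptions (empty if valid).
#' @export
validate_cohort <- function(cohort) {
  out <- character(0)
  note <- function(tr, msg)
    sprintf("%s/%s [%s]: %s", tr$replicate_id, tr$cell_id, tr$channel, msg)
  for (tr in cohort$traces) {
    n <- length(tr$times)
    if (n != length(tr$values))
      out <- c(out, note(tr, "times and values differ in length"))
    d <- diff(tr$times)
    if (any(d <= 0)) {
      out <- c(out, note(tr, "times not strictly increasing"))
    } else if (length(d) && max(d) - min(d) > TIME_TOL) {
      out <- c(out, note(tr, "non-uniform sampling step"))
    }
    if (any(!is.finite(tr$values)))
      out <- c(out, note(tr, "non-finite intensity values"))
    if (any(tr$values < 0, na.rm = TRUE))
      out <- c(out, note(tr, "negative intensity on the raw scale"))
    lo <- min(tr$times); hi <- max(tr$times)
    ev_in <- function(ev) all(ev >= lo - TIME_TOL & ev <= hi + TIME_TOL)
    if (!ev_in(tr$mitosis_times))
      out <- c(out, note(tr, "mitosis time outside the sampled span"))
    if (!ev_in(tr$sphase_times))
      out <- c(out, note(tr, "S-phase time outside the sampled span"))
    if (is.unsorted(tr$mitosis_times))
      out <- c(out, note(tr, "mitosis times not sorted"))
    if (is.unsorted(tr$sphase_times))
      out <- c(out, note(tr, "S-phase times not sorted"))
  }
  if (length(cohort$traces)) {
    dts <- vapply(cohort$traces, function(tr) tr$dt, numeric(1))
    if (max(dts) - min(dts) > TIME_TOL)
      out <- c(out, "cohort: traces do not share a common dt")
  }
  out
}

## Nearest-sample index for a real-valued event time; ties toward the
## earlier sample (events are real-valued hours, snapping happens only where
## an index is needed).
snap_index <- function(times, t) {
  d <- abs(times - t)
  m <- min(d)
  which(d <= m + TIME_TOL)[1]
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline: the circadian-level and
#' ultradian period bands, the dominant-period search range, the two
#' detrending windows that isolate each band, the event-coincidence
#' tolerance and the dip-detection prominence.
#'
#' @param circadian_band,ultradian_band Two-element `c(low, high)` period
#'   bands in hours. Defaults 20-30 h and 4-8 h.
#' @param period_search Dominant-period search range in hours.
#' @param detrend_window_long Moving-average window (h) whose subtraction
#'   isolates circadian-level oscillations; default 40 h.
#' @param detrend_window_short Window (h) isolating ultradian oscillations;
#'   default 12 h.
#' @param coincidence_tol Event-coincidence tolerance in hours; default 1 h.
#' @param dip_prominence Extremum prominence threshold in z-units.
#' @param seed Integer seed driving all randomness downstream.
#' @return A list of class `hes_config`.
#' @export
analysis_config <- function(circadian_band = c(20, 30),
                            ultradian_band = c(4, 8),
                            period_search = c(3, 40),
                            detrend_window_long = 40,
                            detrend_window_short = 12,
                            coincidence_tol = 1.0,
                            dip_prominence = 0.5,
                            seed = 1L) {
  cfg <- list(circadian_band = as.numeric(circadian_band),
              ultradian_band = as.numeric(ultradian_band),
              period_search = as.numeric(period_search),
              detrend_window_long = as.numeric(detrend_window_long),
              detrend_window_short = as.numeric(detrend_window_short),
              coincidence_tol = as.numeric(coincidence_tol),
              dip_prominence = as.numeric(dip_prominence),
              seed = as.integer(seed))
  check_config(cfg)
  structure(cfg, class = "hes_config")
}

check_config <- function(cfg) {
  for (nm in c("circadian_band", "ultradian_band", "period_search")) {
    b <- cfg[[nm]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] <= 0 || b[1] >= b[2])
      stop(sprintf("schema error: %s must satisfy 0 < low < high", nm))
  }
  for (nm in c("detrend_window_long", "detrend_window_short",
               "coincidence_tol", "dip_prominence")) {
    v <- cfg[[nm]]
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("schema error: %s must be a positive scalar", nm))
  }
  invisible(cfg)
}
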