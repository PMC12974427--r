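## Peak/dip event detection, amplitude and fold-change statistics,
## dual-reporter phase relations, reentry and division-fraction
## statistics, and raw intensity-level summaries.

#' Detect alternating peaks and dips by prominence
#'
#' Local extrema are filtered by topographic prominence (for a peak, the
#' drop to the highest of the two saddle minima separating it from higher
#' terrain; symmetrically for dips) and the surviving events are reduced
#' to a strictly alternating peak/dip sequence, keeping the most extreme
#' event of any same-kind run. Ties in prominence break toward earlier
#' time.
#'
#' @param trace An `hes_trace` (usually detrended); needs >= 5 samples.
#' @param prominence Minimum prominence, in the units of the trace.
#' @return A data frame of events (`kind`, `time`, `value`,
#'   `prominence`), possibly empty.
#' @export
detect_extrema <- function(trace, prominence) {
  x <- trace$values; t <- trace$times
  if (length(x) < 5) stop("length error: need at least 5 samples")
  pk <- find_prominent(x, prominence)
  dp <- find_prominent(-x, prominence)
  ev <- rbind(
    if (length(pk$idx)) data.frame(kind = "peak", idx = pk$idx,
                                   prominence = pk$prom),
    if (length(dp$idx)) data.frame(kind = "dip", idx = dp$idx,
                                   prominence = dp$prom))
  if (is.null(ev) || !nrow(ev))
    return(data.frame(kind = character(0), time = numeric(0),
                      value = numeric(0), prominence = numeric(0)))
  ev <- ev[order(ev$idx), , drop = FALSE]
  ## enforce alternation: within a run of equal kinds keep the most extreme
  keep <- rep(TRUE, nrow(ev))
  run_start <- 1
  for (i in seq_len(nrow(ev))) {
    if (i < nrow(ev) && ev$kind[i + 1] == ev$kind[run_start]) next
    run <- run_start:i
    if (length(run) > 1) {
      v <- x[ev$idx[run]]
      best <- if (ev$kind[run_start] == "peak") run[which.max(v)]
              else run[which.min(v)]
      keep[setdiff(run, best)] <- FALSE
    }
    run_start <- i + 1
  }
  ev <- ev[keep, , drop = FALSE]
  data.frame(kind = ev$kind, time = t[ev$idx], value = x[ev$idx],
             prominence = ev$prominence, stringsAsFactors = FALSE)
}

## Local maxima of x with topographic prominence >= p; interior samples
## only. Ties toward earlier time come free from which.max semantics.
find_prominent <- function(x, p) {
  n <- length(x)
  i <- 2:(n - 1)
  cand <- i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
  if (!length(cand)) return(list(idx = integer(0), prom = numeric(0)))
  prom <- vapply(cand, function(j) {
    h <- x[j]
    left <- x[seq_len(j - 1)]
    higher_l <- which(left > h)
    base_l <- if (length(higher_l)) min(x[(max(higher_l) + 1):(j - 1)])
              else min(left)
    right <- x[(j + 1):n]
    higher_r <- which(right > h)
    base_r <- if (length(higher_r)) min(x[(j + 1):(j + min(higher_r) - 1)])
              else min(right)
    h - max(base_l, base_r)
  }, numeric(1))
  sel <- prom >= p
  list(idx = cand[sel], prom = prom[sel])
}

#' Peak-to-dip amplitudes from an alternating event sequence
#'
#' @param events Data frame from [detect_extrema()]; kinds must
#'   alternate.
#' @return Numeric vector: `value(peak) - value(next dip)` for every
#'   adjacent peak-dip pair (empty for empty input).
#' @export
peak_dip_amplitudes <- function(events) {
  if (!nrow(events)) return(numeric(0))
  k <- events$kind
  if (any(k[-1] == k[-length(k)]))
    stop("pairing error: events do not alternate")
  i <- which(k == "peak")
  i <- i[i < nrow(events)]
  events$value[i] - events$value[i + 1]
}

#' Peak-dip amplitudes across a cohort on a band-isolated scale
#'
#' Band-isolates each raw trace, detects extrema with a prominence of
#' `config$dip_prominence` z-units expressed on the trace's own scale
#' (prominence times the detrended standard deviation) and pools all
#' peak-to-dip amplitudes in arbitrary units.
#'
#' @param cohort A [new_cohort()] object of raw traces.
#' @param band_label `"circadian"` or `"ultradian"`.
#' @param config An [analysis_config()].
#' @return Numeric vector of amplitudes (a.u.).
#' @export
cohort_amplitudes <- function(cohort, band_label = c("circadian", "ultradian"),
                              config = analysis_config()) {
  band_label <- match.arg(band_label)
  iso <- paste0(band_label, "_isolated")
  unlist(lapply(cohort$traces, function(tr) {
    d <- isolate_band(tr, iso, config)
    s <- stats::sd(d$values)
    if (!is.finite(s) || s <= 0) return(numeric(0))
    peak_dip_amplitudes(detect_extrema(d, config$dip_prominence * s))
  }))
}

#' Fold-change between the value at release and the post-release minimum
#'
#' The minimum is taken over the window from release to the first
#' post-release mitosis, or over the first 15 h after release when the
#' cell does not divide; the release sample is included in the window, so
#' the fold is always >= 1.
#'
#' @param trace An `hes_trace` carrying a release time (or one supplied
#'   via `release_time`).
#' @param release_time Optional override, hours.
#' @param nodiv_window Window used for non-dividing cells (h).
#' @return The fold-change (value at release / window minimum).
#' @export
release_dip_foldchange <- function(trace, release_time = trace$release_time,
                                   nodiv_window = 15) {
  if (is.na(release_time)) stop("annotation error: no release time")
  if (release_time > max(trace$times) || release_time < min(trace$times))
    stop("range error: release time outside the trace")
  m_after <- trace$mitosis_times[trace$mitosis_times > release_time]
  t_end <- if (length(m_after)) m_after[1] else
    min(release_time + nodiv_window, max(trace$times))
  i0 <- snap_index(trace$times, release_time)
  idx <- trace$times >= trace$times[i0] - TIME_TOL &
    trace$times <= t_end + TIME_TOL
  trace$values[i0] / min(trace$values[idx])
}

#' Time of the post-release HES1 dip
#'
#' The minimum, within the 15 h window after release (release sample
#' excluded), of the trace after light moving-average smoothing (1.5 h)
#' that suppresses sample-level noise jitter around the flat dip bottom;
#' used to pair the reentry dip with the S-phase onset.
#'
#' @param trace An `hes_trace` with a release time.
#' @param window Search window after release, hours.
#' @param smooth Smoothing window in hours.
#' @return Dip time in hours.
#' @export
release_dip_time <- function(trace, window = 15, smooth = 1.5) {
  if (is.na(trace$release_time)) stop("annotation error: no release time")
  k <- max(1L, as.integer(floor(smooth / (2 * trace$dt))))
  sm <- moving_average(trace$values, k)
  idx <- trace$times > trace$release_time &
    trace$times <= trace$release_time + window
  tt <- trace$times[idx]
  tt[which.min(sm[idx])]
}

## Extract event times of one kind from a trace.
events_of_kind <- function(trace, kind) {
  switch(kind,
         mitosis = trace$mitosis_times,
         sphase_onset = trace$sphase_times,
         dip = tryCatch(release_dip_time(trace), error = function(e) numeric(0)),
         cdk2_max = cdk2_max_times(trace),
         p21_decline = p21_decline_times(trace),
         stop("unknown event kind: ", kind))
}

## CDK2 activity maxima: prominent peaks of the lightly smoothed trace
## (one pulse per G1/S passage).
cdk2_max_times <- function(trace) {
  sm <- moving_average(trace$values, max(1L, as.integer(round(1 / trace$dt))))
  pk <- find_prominent(sm, 0.5 * stats::sd(sm))
  trace$times[pk$idx]
}

## p21 decline times: local minima of the smoothed derivative that fall
## below half the steepest decline (one sigmoid drop per cycle).
p21_decline_times <- function(trace) {
  sm <- moving_average(trace$values, max(1L, as.integer(round(1 / trace$dt))))
  g <- diff(sm) / trace$dt
  dp <- find_prominent(-g, 0.25 * max(-g))
  idx <- dp$idx[-g[dp$idx] > 0.5 * max(-g)]
  trace$times[idx]
}

#' Pairwise event-phase relations across a cohort
#'
#' For every cell carrying both event kinds (cells lacking either are
#' excluded and counted), each kind-a event is paired with the nearest
#' kind-b event; the offset is `time_b - time_a` and pairs are classified
#' `a_first` / `coincident` / `b_first` with coincidence tolerance `tol`.
#' Event kinds referring to different channels (e.g. `cdk2_max`) are read
#' from the matching channel trace of the same cell.
#'
#' @param cohort A [new_cohort()] object.
#' @param kind_a,kind_b Event kinds: `"dip"`, `"sphase_onset"`,
#'   `"mitosis"`, `"cdk2_max"`, `"p21_decline"`.
#' @param tol Coincidence tolerance in hours.
#' @return A list with the per-pair data frame `pairs`, per-class
#'   `fractions`, the fraction `a_first_or_coincident` and the number of
#'   excluded cells.
#' @export
phase_pairs <- function(cohort, kind_a, kind_b, tol = 1.0) {
  chan_for <- function(kind) switch(kind, cdk2_max = "cdk2",
                                    p21_decline = "p21",
                                    dip = c("hes1_endo", "hes1_total"), NULL)
  cells <- split(cohort$traces,
                 vapply(cohort$traces,
                        function(tr) paste(tr$replicate_id, tr$cell_id),
                        character(1)))
  pairs <- list(); excluded <- 0L
  for (trs in cells) {
    pick <- function(kind) {
      ch <- chan_for(kind)
      cand <- if (is.null(ch)) trs else
        Filter(function(tr) tr$channel %in% ch, trs)
      if (!length(cand)) return(numeric(0))
      events_of_kind(cand[[1]], kind)
    }
    ta <- pick(kind_a); tb <- pick(kind_b)
    if (!length(ta) || !length(tb)) { excluded <- excluded + 1L; next }
    for (a in ta) {
      b <- tb[which.min(abs(tb - a))]
      off <- b - a
      pairs[[length(pairs) + 1]] <- data.frame(
        cell_id = trs[[1]]$cell_id, replicate_id = trs[[1]]$replicate_id,
        time_a = a, time_b = b, offset = off,
        coincidence_class = if (abs(off) <= tol) "coincident"
                            else if (off > tol) "a_first" else "b_first",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(pairs))
    return(list(pairs = data.frame(), fractions = c(a_first = NA, coincident = NA,
                                                    b_first = NA),
                a_first_or_coincident = NA_real_, excluded = excluded))
  df <- do.call(rbind, pairs)
  fr <- prop.table(table(factor(df$coincidence_class,
                                levels = c("a_first", "coincident", "b_first"))))
  list(pairs = df, fractions = c(fr),
       a_first_or_coincident = unname(fr["a_first"] + fr["coincident"]),
       excluded = excluded)
}

#' Cell cycle reentry statistics after release
#'
#' @param cohort A [new_cohort()] of released-regime traces (every trace
#'   must carry a release time).
#' @param window Reentry window in hours (30 h defines "reentry"; 24 h is
#'   the misexpression assay window).
#' @return A list with the `fraction` of cells showing at least one
#'   mitosis in `(release, release + window]`, the per-cell first mitosis
#'   delays and a 1 h-bin timing `histogram`.
#' @export
reentry_stats <- function(cohort, window = 30) {
  cells <- unique_cells(cohort)
  delays <- vapply(cells, function(trs) {
    tr <- trs[[1]]
    if (is.na(tr$release_time)) stop("annotation error: trace lacks release_time")
    m <- tr$mitosis_times[tr$mitosis_times > tr$release_time]
    if (length(m)) m[1] - tr$release_time else NA_real_
  }, numeric(1))
  frac <- mean(!is.na(delays) & delays <= window)
  d <- delays[!is.na(delays) & delays <= window]
  breaks <- seq(0, ceiling(window), by = 1)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE, right = FALSE)
  list(fraction = frac, first_mitosis_delay = delays,
       histogram = data.frame(delay_mid = h$mids, count = h$counts))
}

unique_cells <- function(cohort) {
  split(cohort$traces,
        vapply(cohort$traces,
               function(tr) paste(tr$replicate_id, tr$cell_id), character(1)))
}

#' Fraction of cells with at least k divisions inside a window
#'
#' @param cohort A [new_cohort()] object.
#' @param window Observation window in hours, starting at the trace
#'   start.
#' @param k Minimum number of mitoses.
#' @return Fraction over all cells.
#' @export
division_fractions <- function(cohort, window, k = 1) {
  cells <- unique_cells(cohort)
  if (!length(cells)) return(NA_real_)
  counts <- vapply(cells, function(trs) {
    tr <- trs[[1]]
    t0 <- min(tr$times)
    if (window > max(tr$times) - t0 + TIME_TOL)
      stop("range error: window exceeds the trace span")
    sum(tr$mitosis_times >= t0 & tr$mitosis_times <= t0 + window)
  }, numeric(1))
  mean(counts >= k)
}

#' Raw intensity statistics normalized to a reference cohort
#'
#' Computes per-cell mean, maximum and minimum raw intensity for both
#' cohorts, normalizes each cell's values to the reference cohort's
#' median, and reports the fold-changes of medians (cohort over
#' reference) for each statistic.
#'
#' @param cohort A [new_cohort()] of raw traces.
#' @param reference_cohort Reference [new_cohort()] (e.g. vehicle-treated).
#' @return A list with per-cell statistics for both cohorts (normalized
#'   columns included) and the named `fold_changes` vector
#'   (`mean`, `max`, `min`).
#' @export
intensity_stats <- function(cohort, reference_cohort) {
  if (!length(reference_cohort$traces)) stop("empty reference cohort")
  per_cell <- function(co) {
    cells <- unique_cells(co)
    do.call(rbind, lapply(cells, function(trs) {
      tr <- trs[[1]]
      data.frame(replicate_id = tr$replicate_id, cell_id = tr$cell_id,
                 mean = mean(tr$values), max = max(tr$values),
                 min = min(tr$values), stringsAsFactors = FALSE)
    }))
  }
  a <- per_cell(cohort); b <- per_cell(reference_cohort)
  ref_med <- vapply(c("mean", "max", "min"),
                    function(s) stats::median(b[[s]]), numeric(1))
  for (s in c("mean", "max", "min")) {
    a[[paste0(s, "_norm")]] <- a[[s]] / ref_med[[s]]
    b[[paste0(s, "_norm")]] <- b[[s]] / ref_med[[s]]
  }
  folds <- vapply(c("mean", "max", "min"),
                  function(s) stats::median(a[[s]]) / ref_med[[s]], numeric(1))
  rownames(a) <- rownames(b) <- NULL
  list(cells = a, reference_cells = b, fold_changes = folds)
}

#' Mean exogenous-reporter traces grouped by division fate
#'
#' Groups the cells of a misexpression-assay cohort into dividers and
#' nondividers using the ground-truth mitosis annotations and averages
#' the requested channel.
#'
#' @param cohort A misexpression-regime [new_cohort()].
#' @param channel Channel to average (default the exogenous reporter).
#' @return A data frame `time`, `divider_mean`, `nondivider_mean`,
#'   `n_dividers`, `n_nondividers`.
#' @export
tet_fate_profiles <- function(cohort, channel = "hes1_exo") {
  trs <- Filter(function(tr) tr$channel == channel, cohort$traces)
  if (!length(trs)) stop("no traces on channel ", channel)
  div <- vapply(trs, function(tr)
    any(tr$mitosis_times > tr$release_time), logical(1))
  mrow <- function(sel) if (any(sel))
    colMeans(do.call(rbind, lapply(trs[sel], function(tr) tr$values)))
    else rep(NA_real_, length(trs[[1]]$times))
  data.frame(time = trs[[1]]$times,
             divider_mean = mrow(div), nondivider_mean = mrow(!div),
             n_dividers = sum(div), n_nondividers = sum(!div))
}
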