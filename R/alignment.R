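## Mitosis-to-mitosis segmentation, pseudo-time warping and dip-timing
## extraction. Pseudo-synchronization rescales each cycle to percent of
## its own duration so asynchronous cell cycle-locked oscillations align
## across the population, whereas real-time averaging of the same traces
## is flat.

#' Split a trace into mitosis-to-mitosis cycle segments
#'
#' One segment per consecutive annotated mitosis pair. Segments with a
#' cycle length outside 6-80 h are flagged (`flagged = TRUE`) but kept.
#'
#' @param trace An `hes_trace`.
#' @return A list of `hes_segment` objects (empty when the trace has
#'   fewer than two mitoses).
#' @export
segment_cycles <- function(trace) {
  m <- trace$mitosis_times
  if (length(m) < 2) return(list())
  lapply(seq_len(length(m) - 1), function(j) {
    s <- m[j]; e <- m[j + 1]
    idx <- trace$times >= s - TIME_TOL & trace$times <= e + TIME_TOL
    structure(list(cell_id = trace$cell_id,
                   replicate_id = trace$replicate_id,
                   start_mitosis = s, end_mitosis = e, T = e - s,
                   times = trace$times[idx], values = trace$values[idx],
                   flagged = (e - s) < 6 || (e - s) > 80),
              class = "hes_segment")
  })
}

#' Resample a cycle segment onto a pseudo-time grid
#'
#' Linear interpolation onto `n_bins + 1` equally spaced cycle fractions
#' between the two bounding mitoses (0% to 100% of the cycle); endpoints
#' take the boundary sample values.
#'
#' @param segment An `hes_segment` with at least 4 samples.
#' @param n_bins Number of pseudo-time bins (default 100).
#' @return Numeric vector of length `n_bins + 1`.
#' @export
warp_pseudotime <- function(segment, n_bins = 100) {
  if (length(segment$times) < 4)
    stop("length error: segment needs at least 4 samples")
  xout <- seq(segment$start_mitosis, segment$end_mitosis,
              length.out = n_bins + 1)
  stats::approx(segment$times, segment$values, xout = xout, rule = 2)$y
}

zscore_vec <- function(x) {
  s <- stats::sd(x) * sqrt((length(x) - 1) / length(x))
  if (s > 0) (x - mean(x)) / s else rep(0, length(x))
}

#' Population mean profile in real or pseudo time
#'
#' In `"real_time"` mode whole traces are z-scored and averaged sample by
#' sample on the shared time axis; in `"pseudo_time"` mode each
#' mitosis-to-mitosis segment is z-scored, warped to percent-of-cycle and
#' averaged across segments.
#'
#' @param cohort A [new_cohort()] object.
#' @param mode `"real_time"` or `"pseudo_time"`.
#' @param n_bins Pseudo-time bins.
#' @return A data frame with the profile axis (`time` in hours or `frac`
#'   in cycle fraction), `mean`, `sd` and the number of series averaged.
#' @export
population_mean <- function(cohort, mode = c("real_time", "pseudo_time"),
                            n_bins = 100) {
  mode <- match.arg(mode)
  if (mode == "real_time") {
    zs <- lapply(cohort$traces, zscore_trace)
    m <- do.call(rbind, lapply(zs, function(tr) tr$values))
    if (nrow(m) < 5) stop("need at least 5 traces")
    data.frame(time = cohort$traces[[1]]$times,
               mean = colMeans(m), sd = apply(m, 2, stats::sd),
               n = nrow(m))
  } else {
    segs <- unlist(lapply(cohort$traces, segment_cycles), recursive = FALSE)
    segs <- Filter(function(s) !s$flagged && length(s$times) >= 4, segs)
    if (length(segs) < 5) stop("need at least 5 segments")
    m <- do.call(rbind, lapply(segs, function(s)
      warp_pseudotime(structure(modifyList(s, list(values = zscore_vec(s$values))),
                                class = class(s)), n_bins)))
    data.frame(frac = seq(0, 1, length.out = n_bins + 1),
               mean = colMeans(m), sd = apply(m, 2, stats::sd),
               n = nrow(m))
  }
}

#' Two-generation alignment and dip timing before the final mitosis
#'
#' For every cell with at least three annotated mitoses the last three
#' define a mother and a daughter generation. Traces are circadian-level
#' isolated and z-scored, aligned so the final mitosis sits at time 0, and
#' the per-cell dip time is the interior minimum of the daughter-generation
#' segment, in negative hours before the final mitosis. Cells whose
#' minimum falls on a segment boundary are excluded (boundary minima are
#' artifacts of mitotic signal loss).
#'
#' @param cohort A [new_cohort()] object.
#' @param config An [analysis_config()].
#' @return A list with `dips` (per-cell dip times and cycle lengths),
#'   `excluded` (count of boundary-minimum cells), a kernel `density`
#'   summary of dip times and `aligned`, the per-cell z-scored series on
#'   the mitosis-aligned axis.
#' @export
dip_timing <- function(cohort, config = analysis_config()) {
  rows <- list(); aligned <- list(); excluded <- 0L
  for (tr in cohort$traces) {
    m <- tr$mitosis_times
    if (length(m) < 3) next
    m3 <- utils::tail(m, 3)
    d <- zscore_trace(isolate_band(tr, "circadian_isolated", config))
    idx <- d$times >= m3[1] - TIME_TOL & d$times <= m3[3] + TIME_TOL
    tt <- d$times[idx]; vv <- d$values[idx]
    seg <- tt >= m3[2] - TIME_TOL
    st <- tt[seg]; sv <- vv[seg]
    if (length(sv) < 3) next
    imin <- which.min(sv)
    if (imin == 1L || imin == length(sv)) { excluded <- excluded + 1L; next }
    rows[[length(rows) + 1]] <- data.frame(
      replicate_id = tr$replicate_id, cell_id = tr$cell_id,
      dip_time = st[imin] - m3[3],
      T_mother = m3[2] - m3[1], T_daughter = m3[3] - m3[2],
      stringsAsFactors = FALSE)
    aligned[[length(aligned) + 1]] <-
      data.frame(cell_id = tr$cell_id, time_rel = tt - m3[3], value = vv)
  }
  if (!length(rows))
    return(list(dips = data.frame(), excluded = excluded,
                density = NULL, aligned = list()))
  dips <- do.call(rbind, rows)
  dens <- stats::density(dips$dip_time)
  list(dips = dips, excluded = excluded,
       density = data.frame(dip_time = dens$x, density = dens$y),
       aligned = aligned)
}
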