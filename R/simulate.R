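## Synthetic cohort generator.
##
## Proliferative cells carry a cell cycle-locked raised-cosine component
## whose minimum (the "dip") falls a per-cell 10-14 h before the next
## mitosis, plus a weak nested ultradian sinusoid; arrested cells lose the
## cycle-locked component, sit at a 1.4-fold elevated baseline and show
## relatively enhanced ultradian fluctuations with deepened dips; released
## cells show a synchronous post-release dip (mean fold-change 2.2) and
## reenter the cycle with a synchronous-wave-plus-stragglers timing
## distribution; misexpression cells add an anti-phase exogenous channel
## and divide only when total HES1 falls below a threshold fraction of its
## release value within 15 h.

## Ornstein-Uhlenbeck noise, stationary sd `sd`, correlation time `tau` h.
ou_process <- function(n, dt, sd, tau) {
  if (sd <= 0) return(numeric(n))
  x <- numeric(n)
  a <- exp(-dt / tau)
  b <- sd * sqrt(1 - a^2)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    z <- stats::rnorm(n - 1)
    for (i in 2:n) x[i] <- a * x[i - 1] + b * z[i - 1]
  }
  x
}

## Lognormal with a stated median: meanlog = log(median).
rlnorm_med <- function(n, median, sigma_log) {
  if (sigma_log <= 0) return(rep(median, n))
  stats::rlnorm(n, meanlog = log(median), sdlog = sigma_log)
}

## Reentry delays: mixture of a synchronous wave (truncated normal) and a
## slow straggler tail (lognormal).
r_reentry <- function(n, p) {
  fast <- stats::runif(n) < p$reentry_fast_frac
  out <- numeric(n)
  nf <- sum(fast)
  if (nf) {
    x <- stats::rnorm(nf, p$reentry_fast_mean, p$reentry_fast_sd)
    while (any(x < 13))
      x[x < 13] <- stats::rnorm(sum(x < 13), p$reentry_fast_mean,
                                p$reentry_fast_sd)
    out[fast] <- x
  }
  if (n - nf)
    out[!fast] <- rlnorm_med(n - nf, p$reentry_slow_median,
                             p$reentry_slow_sigma_log)
  out
}

## Successive cell cycles from `anchor` (a mitosis time, possibly < 0)
## until past `t_end`; per-cycle dip lead drawn uniformly.
make_cycles <- function(p, anchor, t_end) {
  starts <- numeric(0); lens <- numeric(0); leads <- numeric(0)
  t0 <- anchor
  while (t0 <= t_end) {
    T <- rlnorm_med(1, p$cycle_length_median, p$cycle_length_sigma_log)
    L <- stats::runif(1, p$dip_lead_range[1], p$dip_lead_range[2])
    starts <- c(starts, t0); lens <- c(lens, T); leads <- c(leads, L)
    t0 <- t0 + T
  }
  u_dip <- pmin(pmax(1 - leads / lens, 0.05), 0.95)
  data.frame(start = starts, T = lens, end = starts + lens,
             u_dip = u_dip, t_dip = starts + u_dip * lens)
}

## Cycle-locked waveform over a time grid: -cos(2*pi*(u - u_dip)) per
## cycle, so the minimum sits at cycle fraction u_dip and the maxima fall
## near both mitoses. Times before the first or after the last cycle get NA.
cycle_wave <- function(times, cycles) {
  w <- rep(NA_real_, length(times))
  for (j in seq_len(nrow(cycles))) {
    idx <- times >= cycles$start[j] & times < cycles$end[j]
    if (!any(idx)) next
    u <- (times[idx] - cycles$start[j]) / cycles$T[j]
    w[idx] <- -cos(2 * pi * (u - cycles$u_dip[j]))
  }
  w
}

## Arrested-regime relative fluctuation: ultradian sinusoid plus a
## mean-compensated periodic dip train at the sinusoid minima.
arrest_fluct <- function(times, p, Tu, phi) {
  s <- sin(2 * pi * times / Tu + phi)
  ph <- (times / Tu + phi / (2 * pi) - 0.75) %% 1
  d <- (ph - round(ph)) * Tu                 # hours from nearest dip centre
  w <- p$arrest_dip_width
  dip <- ifelse(abs(d) <= w / 2,
                p$arrest_dip_depth * 0.5 * (1 + cos(2 * pi * d / w)), 0)
  dbar <- p$arrest_dip_depth * w / (2 * Tu)
  p$arrest_ultradian_amplitude * s + dbar - dip
}

## S-phase onset annotations for fully recorded cycles.
cycle_sphases <- function(cycles, p, t_lo, t_hi) {
  keep <- cycles$start >= t_lo - TIME_TOL & cycles$end <= t_hi + TIME_TOL
  cyc <- cycles[keep, , drop = FALSE]
  if (!nrow(cyc)) return(numeric(0))
  ts <- cyc$t_dip + stats::rnorm(nrow(cyc), p$sphase_offset_mean,
                                 p$sphase_offset_sd)
  pmin(pmax(ts, cyc$start + 0.5), cyc$end - 0.5)
}

noise_vec <- function(n, dt, p)
  ou_process(n, dt, p$ou_sd, p$ou_tau) +
    stats::rnorm(n, 0, p$noise_sd)

## -- per-cell builders ------------------------------------------------

sim_cell_proliferative <- function(times, p, ids) {
  dt <- times[2] - times[1]
  Tu <- stats::runif(1, p$ultradian_period_range[1], p$ultradian_period_range[2])
  phi <- stats::runif(1, 0, 2 * pi)
  snd <- stats::runif(1) < p$snd_fraction
  if (snd) {
    det <- p$arrest_level_factor * p$baseline *
      (1 + arrest_fluct(times, p, Tu, phi))
    vals <- pmax(det + noise_vec(length(times), dt, p), 0)
    return(list(new_trace(ids$cell, ids$rep, "proliferative", "hes1_endo",
                          times, vals)))
  }
  T1 <- rlnorm_med(1, p$cycle_length_median, p$cycle_length_sigma_log)
  anchor <- -stats::runif(1) * T1
  cycles <- make_cycles(p, anchor, max(times))
  w <- cycle_wave(times, cycles)
  det <- p$baseline * (1 + p$cc_amplitude * w +
                         p$ultradian_amplitude * sin(2 * pi * times / Tu + phi))
  vals <- pmax(det + noise_vec(length(times), dt, p), 0)
  mits <- cycles$start[cycles$start >= min(times) - TIME_TOL &
                         cycles$start <= max(times) + TIME_TOL]
  sph <- cycle_sphases(cycles, p, min(times), max(times))
  tr <- new_trace(ids$cell, ids$rep, "proliferative", "hes1_endo",
                  times, vals, mitosis_times = mits, sphase_times = sph)
  co_channel_traces(tr, times, cycles, p, dt)
}

sim_cell_arrested <- function(times, p, ids) {
  dt <- times[2] - times[1]
  Tu <- stats::runif(1, p$ultradian_period_range[1], p$ultradian_period_range[2])
  phi <- stats::runif(1, 0, 2 * pi)
  det <- p$arrest_level_factor * p$baseline *
    (1 + arrest_fluct(times, p, Tu, phi))
  vals <- pmax(det + noise_vec(length(times), dt, p), 0)
  list(new_trace(ids$cell, ids$rep, "arrested", "hes1_endo", times, vals))
}

## Deterministic released-cell curve pieces shared by the released and
## misexpression regimes.
## Post-release curve: a slowly drifting envelope from the value at
## release toward the pre-mitotic peak, minus a localized raised-cosine
## dip (width ~10 h) bottoming at value_at_release / fold at the dip
## time. The localized dip keeps realistic curvature at the minimum.
released_det <- function(times, p, Tu, phi, rel, t_dip, M1) {
  LB <- p$arrest_level_factor * p$baseline
  V0 <- LB * (1 + arrest_fluct(rel, p, Tu, phi))
  bottom <- V0 / p$release_dip_foldchange
  Btop <- p$baseline * (1 + p$cc_amplitude)
  det <- numeric(length(times))
  pre <- times < rel
  det[pre] <- LB * (1 + arrest_fluct(times[pre], p, Tu, phi))
  seg <- times >= rel & times <= M1
  env <- Btop + (V0 - Btop) *
    0.5 * (1 + cos(pi * (times[seg] - rel) / (M1 - rel)))
  env_dip <- Btop + (V0 - Btop) *
    0.5 * (1 + cos(pi * (t_dip - rel) / (M1 - rel)))
  w <- 2 * min(t_dip - rel, M1 - t_dip, 5)     # dip half-width <= 5 h
  tau <- times[seg] - t_dip
  bump <- ifelse(abs(tau) <= w / 2,
                 (env_dip - bottom) * 0.5 * (1 + cos(2 * pi * tau / w)), 0)
  det[seg] <- env - bump
  list(det = det, V0 = V0, bottom = bottom, Btop = Btop)
}

sim_cell_released <- function(times, p, ids, condition = "released") {
  dt <- times[2] - times[1]
  Tu <- stats::runif(1, p$ultradian_period_range[1], p$ultradian_period_range[2])
  phi <- stats::runif(1, 0, 2 * pi)
  rel <- p$release_time
  t_dip <- rel + stats::runif(1, p$release_dip_time_range[1],
                              p$release_dip_time_range[2])
  M1 <- max(rel + r_reentry(1, p), t_dip + 2)
  parts <- released_det(times, p, Tu, phi, rel, t_dip, M1)
  det <- parts$det
  cycles <- make_cycles(p, M1, max(times))
  post <- times > M1
  if (any(post)) {
    w <- cycle_wave(times[post], cycles)
    det[post] <- p$baseline *
      (1 + p$cc_amplitude * w +
         p$ultradian_amplitude * sin(2 * pi * times[post] / Tu + phi))
  }
  vals <- pmax(det + noise_vec(length(times), dt, p), 0)
  mits <- cycles$start[cycles$start <= max(times) + TIME_TOL]
  sph0 <- min(max(t_dip + stats::rnorm(1, p$sphase_offset_mean,
                                       p$sphase_offset_sd), rel + 0.5),
              M1 - 0.5)
  sph <- c(sph0, cycle_sphases(cycles, p, rel, max(times)))
  sph <- sph[sph <= max(times)]
  tr <- new_trace(ids$cell, ids$rep, condition, "hes1_endo", times, vals,
                  mitosis_times = mits, sphase_times = sph,
                  release_time = rel)
  rel_cycles <- rbind(
    data.frame(start = rel, T = M1 - rel, end = M1,
               u_dip = (t_dip - rel) / (M1 - rel), t_dip = t_dip),
    cycles)
  co_channel_traces(tr, times, rel_cycles, p, dt)
}

sim_cell_misexpression <- function(times, p, ids) {
  dt <- times[2] - times[1]
  Tu <- stats::runif(1, p$ultradian_period_range[1], p$ultradian_period_range[2])
  phi <- stats::runif(1, 0, 2 * pi)
  rel <- p$release_time
  t_dip <- rel + stats::runif(1, p$release_dip_time_range[1],
                              p$release_dip_time_range[2])
  M1 <- max(rel + r_reentry(1, p), t_dip + 2)
  E <- rlnorm_med(1, p$exo_amp_median, p$exo_amp_sigma_log)
  sph0 <- t_dip + stats::rnorm(1, p$sphase_offset_mean, p$sphase_offset_sd)
  n <- length(times)
  noise_endo <- noise_vec(n, dt, p)
  noise_exo <- stats::rnorm(n, 0, p$noise_sd)

  parts <- released_det(times, p, Tu, phi, rel, t_dip, M1)
  endo_div <- parts$det
  cycles <- make_cycles(p, M1, max(times))
  post <- times > M1
  wpost <- if (any(post)) cycle_wave(times[post], cycles) else numeric(0)
  if (any(post))
    endo_div[post] <- p$baseline *
      (1 + p$cc_amplitude * wpost +
         p$ultradian_amplitude * sin(2 * pi * times[post] / Tu + phi))

  ## exogenous channel: induced at release, anti-phase to the endogenous dip
  exo_div <- numeric(n)
  seg <- times >= rel & times <= t_dip
  exo_div[seg] <- E * 0.5 * (1 - cos(pi * (times[seg] - rel) / (t_dip - rel)))
  seg <- times > t_dip & times <= M1
  exo_div[seg] <- E * pmin(pmax((parts$Btop - endo_div[seg]) /
                                  (parts$Btop - parts$bottom), 0), 1)
  if (any(post)) exo_div[post] <- E * (1 - wpost) / 2

  total_div <- pmax(endo_div + noise_endo, 0) + pmax(exo_div + noise_exo, 0)
  in_gate <- times > rel & times <= rel + 15
  v_rel <- total_div[snap_index(times, rel)]
  divides <- min(total_div[in_gate]) < p$dip_gate_threshold * v_rel

  if (divides) {
    endo <- pmax(endo_div + noise_endo, 0)
    exo <- pmax(exo_div + noise_exo, 0)
    mits <- cycles$start[cycles$start <= max(times) + TIME_TOL]
    sph <- min(max(sph0, rel + 0.5), M1 - 0.5)
  } else {
    ## nondivider: sustained exogenous HES1 keeps the endogenous channel
    ## repressed (anti-correlated), so the total profile stays flat
    LB <- p$arrest_level_factor * p$baseline
    plateau <- max(parts$bottom, LB - E)
    endo_det <- parts$det
    seg <- times > t_dip & times <= t_dip + 8
    endo_det[seg] <- parts$bottom + (plateau - parts$bottom) *
      0.5 * (1 - cos(pi * (times[seg] - t_dip) / 8))
    endo_det[times > t_dip + 8] <- plateau
    exo_det <- numeric(n)
    seg <- times >= rel & times <= t_dip
    exo_det[seg] <- E * 0.5 * (1 - cos(pi * (times[seg] - rel) / (t_dip - rel)))
    exo_det[times > t_dip] <- E
    endo <- pmax(endo_det + noise_endo, 0)
    exo <- pmax(exo_det + noise_exo, 0)
    mits <- numeric(0)
    sph <- numeric(0)
  }
  total <- endo + exo
  mk <- function(ch, v)
    new_trace(ids$cell, ids$rep, "misexpression", ch, times, v,
              mitosis_times = mits, sphase_times = sph, release_time = rel)
  list(mk("hes1_endo", endo), mk("hes1_exo", exo), mk("hes1_total", total))
}

sim_cell_control <- function(times, p, ids) {
  dt <- times[2] - times[1]
  det <- p$baseline + p$drift_slope * times
  vals <- pmax(det + noise_vec(length(times), dt, p), 0)
  list(new_trace(ids$cell, ids$rep, "control_nls", "control", times, vals))
}

## CDK2-activity and p21 co-reporter channels derived from the cell's
## ground-truth cycle structure (CDK2 pulse maximal at S-phase onset; p21
## declining shortly after the HES1 dip).
co_channel_traces <- function(tr, times, cycles, p, dt) {
  out <- list(tr)
  if (!is.null(p$channels) && "cdk2" %in% p$channels) {
    cdk2 <- rep(0.3, length(times))
    for (ts in tr$sphase_times)
      cdk2 <- cdk2 + 1.2 * exp(-(times - ts)^2 / (2 * 2^2))
    cdk2 <- pmax(cdk2 + stats::rnorm(length(times), 0, 0.03), 0)
    out <- c(out, list(new_trace(tr$cell_id, tr$replicate_id, tr$condition,
                                 "cdk2", times, cdk2,
                                 mitosis_times = tr$mitosis_times,
                                 sphase_times = tr$sphase_times,
                                 release_time = tr$release_time)))
  }
  if (!is.null(p$channels) && "p21" %in% p$channels) {
    p21 <- rep(1.0, length(times))
    for (j in seq_len(nrow(cycles))) {
      idx <- times >= cycles$start[j] & times < cycles$end[j]
      if (!any(idx)) next
      td <- cycles$t_dip[j] + stats::rnorm(1, p$p21_offset_mean,
                                           p$p21_offset_sd)
      p21[idx] <- 0.2 + 0.8 / (1 + exp((times[idx] - td) / 0.5))
    }
    p21 <- pmax(p21 + stats::rnorm(length(times), 0, 0.03), 0)
    out <- c(out, list(new_trace(tr$cell_id, tr$replicate_id, tr$condition,
                                 "p21", times, p21,
                                 mitosis_times = tr$mitosis_times,
                                 sphase_times = tr$sphase_times,
                                 release_time = tr$release_time)))
  }
  out
}

#' Simulate a synthetic cohort for one regime
#'
#' Generates `n_replicates` x `n_cells` single-cell traces under the given
#' regime with all ground-truth annotations (mitoses, S-phase onsets,
#' release time) recorded. The same seed and parameters always yield an
#' identical cohort.
#'
#' @param regime Regime name (see [regime_params()]) or an `hes_params`
#'   object.
#' @param n_cells Cells per replicate (>= 0).
#' @param n_replicates Number of replicates.
#' @param duration Recording span in hours.
#' @param dt Sampling interval in hours (default 0.25 h).
#' @param seed Integer seed.
#' @param channels Extra co-reporter channels to simulate alongside the
#'   HES1 channel: any of `"cdk2"`, `"p21"` (proliferative and released
#'   regimes only).
#' @param ... Parameter overrides forwarded to [regime_params()] when
#'   `regime` is a name.
#' @return A [new_cohort()] with provenance recording parameters and seed.
#' @export
simulate_cohort <- function(regime, n_cells, n_replicates = 1,
                            duration = 96, dt = 0.25, seed = 1L,
                            channels = character(0), ...) {
  p <- if (inherits(regime, "hes_params")) regime else
    regime_params(regime, ...)
  if (n_cells < 0) stop("parameter error: n_cells must be >= 0")
  if (dt <= 0) stop("parameter error: dt must be > 0")
  if (duration / dt < 1) stop("parameter error: need at least 2 samples")
  p$channels <- channels
  set.seed(as.integer(seed))
  times <- seq(0, duration, by = dt)
  builder <- switch(p$regime,
                    proliferative = sim_cell_proliferative,
                    arrested = sim_cell_arrested,
                    released = sim_cell_released,
                    misexpression = sim_cell_misexpression,
                    control_nls = sim_cell_control)
  traces <- list()
  for (r in seq_len(n_replicates)) {
    for (i in seq_len(n_cells)) {
      ids <- list(cell = sprintf("c%03d", i), rep = sprintf("R%d", r))
      traces <- c(traces, builder(times, p, ids))
    }
  }
  prov <- list(regime = p$regime, params = unclass(p), n_cells = n_cells,
               n_replicates = n_replicates, duration = duration, dt = dt,
               seed = as.integer(seed),
               version = as.character(utils::packageVersion("hes1dyn")))
  new_cohort(traces, provenance = prov)
}
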