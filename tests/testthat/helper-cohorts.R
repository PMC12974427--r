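# Small in-code fixtures shared across the suite.

mk_trace <- function(values, dt = 0.25, cell_id = "c1", rep_id = "R1",
                     condition = "proliferative", channel = "hes1_endo",
                     ...) {
  new_trace(cell_id, rep_id, condition, channel,
            seq(0, by = dt, length.out = length(values)), values, ...)
}

sin_trace <- function(period, duration, dt = 0.25, amp = 1, base = 10,
                      phase = 0, ...) {
  t <- seq(0, duration, by = dt)
  mk_trace(base + amp * sin(2 * pi * t / period + phase), dt = dt, ...)
}

# Noise-free proliferative parameters: fixed 24 h cycle, 12 h dip lead,
# no ultradian component, no noise.
noisefree_params <- function(...) {
  regime_params("proliferative", noise_sd = 0, ou_sd = 0,
                ultradian_amplitude = 0, cycle_length_sigma_log = 0,
                cycle_length_median = 24, dip_lead_range = c(12, 12), ...)
}

# Least-squares amplitude of the `period` component over interior samples
# (jointly fitting any `other` periods present so components do not leak),
# used as the closed-form detrending oracle's measurement side.
fit_amplitude <- function(trace, period, margin = 0, other = numeric(0)) {
  t <- trace$times
  keep <- t >= min(t) + margin & t <= max(t) - margin
  y <- trace$values[keep]; t <- t[keep]
  X <- cbind(1, cos(2 * pi * t / period), sin(2 * pi * t / period))
  for (p in other) X <- cbind(X, cos(2 * pi * t / p), sin(2 * pi * t / p))
  b <- stats::lm.fit(X, y)$coefficients
  sqrt(sum(b[2:3]^2))
}

# Memoized full-size pipeline run shared by the end-to-end tests.
.acc_env <- new.env()
acceptance_run <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (is.null(.acc_env[[key]]))
    .acc_env[[key]] <- pipeline_quantities(seed = seed)
  .acc_env[[key]]
}
acc_value <- function(id, seed = 1L) {
  tab <- acceptance_run(seed)
  tab$value[tab$id == id][1]
}
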