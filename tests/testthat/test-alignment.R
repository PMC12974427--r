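test_that("segmentation yields one segment per consecutive mitosis pair", {
  t <- seq(0, 96, by = 0.25)
  tr <- new_trace("c1", "R1", "proliferative", "hes1_endo", t, sin(t) + 2,
                  mitosis_times = c(0, 24))
  segs <- segment_cycles(tr)
  expect_length(segs, 1L)
  expect_equal(segs[[1]]$T, 24)

  tr$mitosis_times <- c(0, 24, 47)
  segs <- segment_cycles(tr)
  expect_length(segs, 2L)
  expect_equal(vapply(segs, function(s) s$T, numeric(1)), c(24, 23))

  tr$mitosis_times <- c(10)
  expect_length(segment_cycles(tr), 0L)

  tr$mitosis_times <- c(0, 3, 90)            # 3 h and 87 h cycles flagged
  expect_true(all(vapply(segment_cycles(tr), function(s) s$flagged,
                         logical(1))))

  # segment count always equals mitoses - 1
  co <- simulate_cohort("proliferative", 10, 1, 120, 0.25, seed = 3)
  for (trc in co$traces)
    if (length(trc$mitosis_times) >= 2)
      expect_length(segment_cycles(trc), length(trc$mitosis_times) - 1L)
})

test_that("generated cycle lengths track the 23.3 h median", {
  co <- simulate_cohort("proliferative", 90, 1, 96, 0.25, seed = 1)
  T <- unlist(lapply(co$traces, function(tr) diff(tr$mitosis_times)))
  expect_equal(stats::median(T), 23.3, tolerance = 0.7 / 23.3)
})

test_that("pseudo-time warping places the noise-free minimum at u_dip", {
  for (case in list(c(T = 24, L = 12), c(T = 20, L = 10), c(T = 28, L = 14))) {
    p <- noisefree_params(cycle_length_median = case[["T"]],
                          dip_lead_range = rep(case[["L"]], 2))
    co <- simulate_cohort(p, 3, 1, 96, 0.25, seed = 5)
    for (tr in co$traces) {
      segs <- segment_cycles(tr)
      for (s in segs[!vapply(segs, function(x) x$flagged, logical(1))]) {
        w <- warp_pseudotime(s, 100)
        expect_length(w, 101L)
        expect_equal(which.min(w) - 1L, 50L, tolerance = 2)
        expect_equal(w[1], s$values[1])
        expect_equal(w[101], s$values[length(s$values)])
      }
    }
  }
  cs <- segment_cycles(new_trace("c", "R", "proliferative", "hes1_endo",
                                 seq(0, 48, 0.25), rep(4, 193),
                                 mitosis_times = c(0, 24)))[[1]]
  expect_identical(warp_pseudotime(cs, 10), rep(4, 11))
  cs$times <- cs$times[1:3]; cs$values <- cs$values[1:3]
  expect_error(warp_pseudotime(cs), "length error")
})

test_that("warping is invariant to uniform time dilation", {
  t <- seq(0, 24, by = 0.25)
  v <- 10 - cos(2 * pi * (t / 24 - 0.5)) * 4
  fast <- segment_cycles(new_trace("c", "R", "proliferative", "hes1_endo",
                                   t, v, mitosis_times = c(0, 24)))[[1]]
  slow <- segment_cycles(new_trace("c", "R", "proliferative", "hes1_endo",
                                   2 * t, v, mitosis_times = c(0, 48)))[[1]]
  expect_equal(warp_pseudotime(fast, 60), warp_pseudotime(slow, 60),
               tolerance = 1e-6)
})

test_that("real-time averaging is flat while pseudo-time reveals the dip", {
  rt <- population_mean(simulate_cohort("proliferative", 90, 3, 96, 0.25,
                                        seed = 1), "real_time")
  expect_lt(diff(range(rt$mean)), 0.3)
  for (s in 1:3) {
    co <- simulate_cohort("proliferative", 90, 1, 96, 0.25, seed = s)
    pt <- population_mean(co, "pseudo_time")
    expect_gt(diff(range(pt$mean)), 1.0)
    amin <- which.min(pt$mean)
    expect_gt(amin, 1L); expect_lt(amin, nrow(pt))   # interior minimum
    rts <- population_mean(co, "real_time")
    expect_lt(diff(range(rts$mean)), 0.3 * diff(range(pt$mean)))
  }
})

test_that("phase-locked cohorts average identically in both modes", {
  t <- seq(0, 96, by = 0.25)
  v <- 20 - cos(2 * pi * (t / 24 - 0.5)) * 6
  trs <- lapply(1:6, function(i)
    new_trace(sprintf("c%d", i), "R1", "proliferative", "hes1_endo", t, v,
              mitosis_times = c(0, 24, 48, 72, 96)))
  co <- new_cohort(trs)
  rt <- population_mean(co, "real_time")
  pt <- population_mean(co, "pseudo_time")
  rt_cycle <- stats::approx(rt$time[rt$time <= 24] / 24,
                            rt$mean[rt$time <= 24], xout = pt$frac)$y
  expect_equal(pt$mean, rt_cycle, tolerance = 0.05)
})

test_that("dip timing recovers the generative lead exactly without noise", {
  co <- simulate_cohort(noisefree_params(), 8, 1, 120, 0.25, seed = 7)
  res <- dip_timing(co)
  expect_gt(nrow(res$dips), 0)
  expect_equal(res$dips$dip_time, rep(-12, nrow(res$dips)), tolerance = 0.3)
})

test_that("default cohorts dip 10-14 h before the final mitosis", {
  leads <- unlist(lapply(1:3, function(s) {
    co <- simulate_cohort("proliferative", 40, 1, 120, 0.25, seed = s)
    -dip_timing(co)$dips$dip_time
  }))
  expect_gt(length(leads), 40)
  expect_gte(stats::median(leads), 10)
  expect_lte(stats::median(leads), 14)
})

test_that("boundary minima are rejected from dip statistics", {
  t <- seq(0, 96, by = 0.25)
  tr <- new_trace("c1", "R1", "proliferative", "hes1_endo", t,
                  exp(t / 40), mitosis_times = c(10, 40, 70))
  res <- dip_timing(new_cohort(list(tr)))
  expect_identical(nrow(res$dips), 0L)
  expect_identical(res$excluded, 1L)
})
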