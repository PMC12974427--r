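test_that("prominence detection finds alternating sinusoid extrema", {
  tr <- sin_trace(24, 96, base = 0)
  ev <- detect_extrema(tr, 0.5)
  expect_identical(sum(ev$kind == "peak"), 4L)
  expect_identical(sum(ev$kind == "dip"), 4L)
  expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)]))
  expect_true(all(ev$prominence >= 0.5))

  ramp <- mk_trace(seq_len(100) / 10)
  expect_identical(nrow(detect_extrema(ramp, 0.5)), 0L)

  set.seed(1)
  noisy <- tr
  noisy$values <- noisy$values + rnorm(length(noisy$values), 0, 0.05)
  expect_identical(nrow(detect_extrema(noisy, 0.5)), nrow(ev))
})

test_that("peak-dip amplitudes halve to the sinusoid amplitude", {
  for (A in c(1, 3.5)) {
    ev <- detect_extrema(sin_trace(24, 96, amp = A, base = 0), A / 2)
    amps <- peak_dip_amplitudes(ev)
    expect_gt(length(amps), 2)
    expect_equal(amps, rep(2 * A, length(amps)), tolerance = 0.01)
  }
  expect_length(peak_dip_amplitudes(
    data.frame(kind = character(0), time = numeric(0),
               value = numeric(0), prominence = numeric(0))), 0L)
  bad <- data.frame(kind = c("peak", "peak"), time = 1:2, value = 1:2,
                    prominence = 1)
  expect_error(peak_dip_amplitudes(bad), "pairing error")
})

test_that("amplitude ordering across regimes matches the arrest phenotype", {
  prolif <- simulate_cohort("proliferative", 40, 1, 96, 0.25, seed = 1)
  arrest <- simulate_cohort("arrested", 40, 1, 96, 0.25, seed = 11)
  a_circ_p <- stats::median(cohort_amplitudes(prolif, "circadian"))
  a_ultra_p <- stats::median(cohort_amplitudes(prolif, "ultradian"))
  a_ultra_a <- stats::median(cohort_amplitudes(arrest, "ultradian"))
  expect_gt(a_ultra_a, a_ultra_p)     # arrest enhances ultradian dips
  expect_gt(a_circ_p, a_ultra_a)      # but they stay below G1/S dips
})

test_that("release fold-change follows its defining ratio and floors at 1", {
  t <- seq(0, 48, by = 0.25)
  tr <- new_trace("c1", "R1", "released", "hes1_endo", t,
                  200 - 100 * exp(-((t - 10)^2) / 8),
                  mitosis_times = 20, release_time = 2)
  expect_equal(release_dip_foldchange(tr), 2, tolerance = 1e-3)

  up <- new_trace("c1", "R1", "released", "hes1_endo", t, 100 + t,
                  release_time = 2)
  expect_equal(release_dip_foldchange(up), 1.0)
  expect_error(release_dip_foldchange(up, release_time = 99), "range error")

  co <- simulate_cohort("released", 40, 1, 96, 0.25, seed = 2)
  folds <- vapply(co$traces, release_dip_foldchange, numeric(1))
  expect_true(all(folds >= 1))
})

test_that("coincidence fractions match the closed-form normal oracle", {
  set.seed(8)
  n <- 2000
  offs <- rnorm(n, 1.0, 1.6)
  t <- seq(0, 40, by = 0.5)
  trs <- lapply(seq_len(n), function(i)
    new_trace(sprintf("c%04d", i), "R1", "released", "hes1_endo", t,
              rep(1, length(t)), mitosis_times = 20,
              sphase_times = min(max(20 + offs[i], 0.5), 39.5)))
  pp <- phase_pairs(new_cohort(trs), "mitosis", "sphase_onset", tol = 1)
  expect_equal(pp$a_first_or_coincident, pnorm(2 / 1.6), tolerance = 0.03)

  # symmetry under swapping kinds: a/b classes exchange
  qq <- phase_pairs(new_cohort(trs), "sphase_onset", "mitosis", tol = 1)
  expect_equal(unname(pp$fractions["coincident"]),
               unname(qq$fractions["coincident"]))
  expect_equal(unname(pp$fractions["a_first"]),
               unname(qq$fractions["b_first"]))

  same <- lapply(1:5, function(i)
    new_trace(sprintf("c%d", i), "R1", "released", "hes1_endo", t,
              rep(1, length(t)), mitosis_times = 12, sphase_times = 12))
  expect_equal(phase_pairs(new_cohort(same), "mitosis", "sphase_onset",
                           1)$fractions[["coincident"]], 1.0)
})

test_that("dual-reporter phase relations place CDK2 and p21 at G1/S", {
  co <- simulate_cohort("released", 25, 1, 72, 0.25, seed = 4,
                        channels = c("cdk2", "p21"))
  cdk <- phase_pairs(co, "dip", "cdk2_max", tol = 1)
  expect_gt(nrow(cdk$pairs), 15)
  # CDK2 activity peaks about an S-phase onset after the HES1 dip
  expect_lt(abs(stats::median(cdk$pairs$offset) - 1), 1.5)
  p21 <- phase_pairs(co, "dip", "p21_decline", tol = 1)
  expect_lt(abs(stats::median(p21$pairs$offset) - 1.5), 2)
})

test_that("reentry fraction and histogram follow the annotations", {
  t <- seq(0, 60, by = 0.25)
  trs <- lapply(1:8, function(i)
    new_trace(sprintf("c%d", i), "R1", "released", "hes1_endo", t,
              rep(1, length(t)), mitosis_times = 20, release_time = 2))
  rs <- reentry_stats(new_cohort(trs), 30)
  expect_equal(rs$fraction, 1.0)
  expect_equal(rs$histogram$count[rs$histogram$delay_mid == 18.5], 8)
  expect_equal(sum(rs$histogram$count), 8L)

  co <- simulate_cohort("released", 60, 1, 96, 0.25, seed = 3)
  fr <- vapply(c(10, 20, 24, 30, 40), function(w)
    reentry_stats(co, w)$fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))          # monotone in the window

  bad <- new_cohort(list(mk_trace(rep(1, 10))))
  expect_error(reentry_stats(bad, 30), "annotation error")
})

test_that("division fractions count mitoses inside the window", {
  t <- seq(0, 110, by = 0.5)
  none <- new_cohort(lapply(1:4, function(i)
    new_trace(sprintf("c%d", i), "R1", "proliferative", "hes1_endo", t,
              rep(1, length(t)))))
  expect_equal(division_fractions(none, 100, 1), 0)

  two <- new_cohort(lapply(1:4, function(i)
    new_trace(sprintf("c%d", i), "R1", "proliferative", "hes1_endo", t,
              rep(1, length(t)), mitosis_times = c(20, 45))))
  expect_equal(division_fractions(two, 100, 1), 1)
  expect_equal(division_fractions(two, 100, 2), 1)
  expect_equal(division_fractions(two, 30, 2), 0)
  expect_error(division_fractions(two, 200, 1), "range error")

  # unselected cultures: a quarter of cells never divide in 100 h
  co <- simulate_cohort("proliferative", 90, 3, 120, 0.25, seed = 7,
                        snd_fraction = 0.25)
  expect_equal(division_fractions(co, 100, 1), 0.75, tolerance = 0.08 / 0.75)
})

test_that("intensity statistics normalize to the reference medians", {
  co <- simulate_cohort("proliferative", 20, 1, 96, 0.25, seed = 5)
  self <- intensity_stats(co, co)
  expect_equal(unname(self$fold_changes), c(1, 1, 1))
  expect_equal(stats::median(self$cells$mean_norm), 1)
  expect_error(intensity_stats(co, new_cohort()), "empty reference")

  arrest <- simulate_cohort("arrested", 90, 3, 96, 0.25, seed = 11)
  prolif <- simulate_cohort("proliferative", 90, 3, 96, 0.25, seed = 1)
  iv <- intensity_stats(arrest, prolif)
  expect_equal(iv$fold_changes[["max"]], 1.1, tolerance = 0.1 / 1.1)
  expect_equal(iv$fold_changes[["min"]], 1.6, tolerance = 0.1 / 1.6)
})

test_that("misexpression fate profiles separate dividers from nondividers", {
  co <- simulate_cohort("misexpression", 60, 1, 72, 0.25, seed = 6)
  fp <- tet_fate_profiles(co)
  expect_gt(fp$n_nondividers[1], fp$n_dividers[1])
  post <- fp$time > 15
  # nondividers sustain high exogenous HES1; dividers barely induce it
  expect_gt(mean(fp$nondivider_mean[post]), 2 * mean(fp$divider_mean[post]))
})
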