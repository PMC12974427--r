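test_that("empty and invalid generator inputs are handled", {
  co <- simulate_cohort("proliferative", 0, 2, 48, 0.25, seed = 1)
  expect_length(co, 0L)
  expect_identical(co$provenance$regime, "proliferative")
  expect_identical(co$provenance$seed, 1L)

  expect_error(simulate_cohort("proliferative", -1, 1, 48, 0.25),
               "parameter error")
  expect_error(simulate_cohort("proliferative", 2, 1, 48, 0),
               "parameter error")
  expect_error(regime_params("arrested", not_a_param = 1), "parameter error")
  expect_error(regime_params("released", dip_gate_threshold = 1.5),
               "parameter error")
})

test_that("noise-free proliferative traces dip exactly 12 h before mitosis", {
  co <- simulate_cohort(noisefree_params(), 6, 1, 96, 0.25, seed = 4)
  p <- regime_params("proliferative")
  for (tr in co$traces) {
    m <- tr$mitosis_times
    expect_gte(length(m), 2L)
    for (j in seq_len(length(m) - 1)) {
      idx <- tr$times >= m[j] & tr$times < m[j + 1]
      tmin <- tr$times[idx][which.min(tr$values[idx])]
      expect_equal(m[j + 1] - tmin, 12, tolerance = 0.25)
      # continuous-time minimum value B(1 - A_cc), sampled within half a step
      expect_lt(min(tr$values[idx]) -
                  p$baseline * (1 - p$cc_amplitude), 0.05)
      expect_gte(min(tr$values[idx]),
                 p$baseline * (1 - p$cc_amplitude) - 1e-9)
    }
  }
})

test_that("same seed and parameters give byte-identical cohorts", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_tracks(simulate_cohort("misexpression", 5, 2, 48, 0.25, seed = 9), p1)
  write_tracks(simulate_cohort("misexpression", 5, 2, 48, 0.25, seed = 9), p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  write_tracks(simulate_cohort("misexpression", 5, 2, 48, 0.25, seed = 10), p2)
  expect_false(identical(unname(tools::md5sum(p1)),
                         unname(tools::md5sum(p2))))
})

test_that("arrested cells sit 1.4-fold above proliferative cells", {
  # oracle: direct means of the raw arrays, before any pipeline step
  prolif <- simulate_cohort("proliferative", 90, 3, 96, 0.25, seed = 1)
  arrest <- simulate_cohort("arrested", 90, 3, 96, 0.25, seed = 11)
  mp <- mean(unlist(lapply(prolif$traces, function(tr) tr$values)))
  ma <- mean(unlist(lapply(arrest$traces, function(tr) tr$values)))
  expect_equal(ma / mp, 1.4, tolerance = 0.05 / 1.4)
})

test_that("released traces are continuous at the release time", {
  co <- simulate_cohort("released", 12, 1, 72, 0.25, seed = 6,
                        noise_sd = 0, ou_sd = 0)
  for (tr in co$traces) {
    i <- which.min(abs(tr$times - tr$release_time))
    jump <- abs(tr$values[i + 1] - tr$values[i])
    neighbor <- max(abs(diff(tr$values[seq(max(1, i - 12), i)])))
    expect_lt(jump, max(3 * neighbor, 1.5))   # one noise sd at defaults
  }
})

test_that("S-phase onsets lie strictly between bounding divisions", {
  for (s in 1:2) {
    for (regime in c("proliferative", "released")) {
      co <- simulate_cohort(regime, 20, 1, 96, 0.25, seed = s)
      for (tr in co$traces) {
        bounds <- sort(c(tr$mitosis_times,
                         if (!is.na(tr$release_time)) tr$release_time))
        for (ts in tr$sphase_times) {
          expect_true(any(bounds < ts))
          lo <- max(bounds[bounds < ts])
          hi <- bounds[bounds > ts]
          # the next boundary may fall beyond the recording
          if (length(hi)) expect_gt(min(hi), ts)
          expect_lt(lo, ts)
        }
      }
    }
  }
})

test_that("shipped defaults carry the anchored study constants", {
  d <- calibrate_defaults()
  expect_named(d, c("proliferative", "arrested", "released",
                    "misexpression", "control_nls"))
  expect_equal(d$proliferative$cycle_length_median, 23.3)
  expect_equal(d$released$release_dip_foldchange, 2.2)
  expect_equal(d$arrested$arrest_level_factor, 1.4)
  expect_equal(d$released$release_dip_time_range, c(8, 10))
  expect_equal(d$proliferative$dip_lead_range, c(10, 14))
})

test_that("misexpression total channel is the sum and is less variable", {
  co <- simulate_cohort("misexpression", 30, 1, 72, 0.25, seed = 8)
  cells <- split(co$traces, vapply(co$traces, function(tr) tr$cell_id,
                                   character(1)))
  less_var <- 0L
  for (trs in cells) {
    ch <- vapply(trs, function(tr) tr$channel, character(1))
    endo <- trs[[which(ch == "hes1_endo")]]
    exo <- trs[[which(ch == "hes1_exo")]]
    tot <- trs[[which(ch == "hes1_total")]]
    expect_equal(tot$values, endo$values + exo$values, tolerance = 1e-12)
    post <- endo$times > endo$release_time
    if (stats::var(tot$values[post]) < stats::var(endo$values[post]))
      less_var <- less_var + 1L
  }
  # anti-phase exogenous expression damps total HES1 variability
  expect_gt(less_var / length(cells), 0.7)
})
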