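# Constructed response shapes for first-peak measurements: Gaussian bumps on
# a flat baseline, pre-stimulus segment included.
make_peak_trace <- function(peaks_ms, amps, width_ms = 2, fs = 10000,
                            stim_onset = 0.02, dur = 0.1, sign = 1) {
  t_ms <- (seq_len(dur * fs) - 1) / fs * 1000
  x <- numeric(length(t_ms))
  for (i in seq_along(peaks_ms)) {
    x <- x + amps[i] * exp(-(t_ms - (stim_onset * 1000 + peaks_ms[i]))^2 /
                             (2 * width_ms^2))
  }
  sign * x
}

test_that("first-peak rule measures the monosynaptic component", {
  fs <- 10000
  tr <- make_peak_trace(10, 150)
  m <- measure_first_peak(tr, 0.02, fs, "outward")
  expect_equal(m$amplitude, 150, tolerance = 1e-2)
  expect_true(m$resolved)
  expect_true(m$responded)

  # two clearly separated peaks: the first (smaller) one is reported
  tr2 <- make_peak_trace(c(8, 25), c(100, 180))
  m2 <- measure_first_peak(tr2, 0.02, fs, "outward")
  expect_equal(m2$amplitude, 100, tolerance = 1e-2)
  expect_true(m2$resolved)

  # shoulder: trough between 100 and 180 shallower than 20% -> unresolved
  tr3 <- make_peak_trace(c(8, 14), c(100, 180), width_ms = 2)
  trough <- min(tr3[(0.0285 * fs):(0.032 * fs)])
  first_amp <- max(tr3[(0.02 * fs):(0.0285 * fs)])
  expect_gt(trough, 0.8 * first_amp)   # fixture sanity: trough is < 20% deep
  m3 <- measure_first_peak(tr3, 0.02, fs, "outward")
  expect_false(m3$resolved)

  # inward polarity measures downward deflections as positive magnitude
  m4 <- measure_first_peak(make_peak_trace(10, 150, sign = -1), 0.02, fs, "inward")
  expect_equal(m4$amplitude, 150, tolerance = 1e-2)

  expect_error(measure_first_peak(tr, 0.02, fs, "outward", blank_ms = 0.2),
               "0.5 ms")
})

test_that("ratio curves preserve length and flag discarded intensities", {
  ser <- gen_evoked_series(noise_rms = 0, seed = 1)
  cur <- compute_ratio_curve(ser$pairs)
  expect_length(cur$ratios, length(ser$truth$intensities))
  expect_true(all(cur$valid))
  expect_equal(cur$ratios, rep(0.5, 8), tolerance = 5e-3)

  # kill the inhibitory response at the lowest intensity
  ser$pairs[[1]]$inhibitory$samples <- numeric(length(ser$pairs[[1]]$inhibitory$samples))
  cur2 <- compute_ratio_curve(ser$pairs)
  expect_equal(cur2$discard_flags[1], "no_inhibitory_response")
  expect_true(is.na(cur2$ratios[1]))
  expect_length(cur2$ratios, 8)

  # all intensities dead -> error
  dead <- lapply(ser$pairs, function(p) {
    p$inhibitory$samples <- numeric(length(p$inhibitory$samples))
    p$excitatory$samples <- numeric(length(p$excitatory$samples))
    p
  })
  expect_error(compute_ratio_curve(dead), "all intensities discarded")
  expect_error(compute_ratio_curve(ser$pairs[1:3]), "4 intensities")
})

test_that("stable-range search matches the exhaustive-search oracle", {
  r1 <- c(5.0, 2.1, 2.0, 1.9, 2.0)
  expect_equal(find_stable_range(make_curve(r1)), stable_range_oracle(r1))
  expect_equal(which(find_stable_range(make_curve(r1))), 2:5)

  r2 <- rep(1.7, 6)
  expect_equal(which(find_stable_range(make_curve(r2))), 1:6)

  r3 <- rep(c(1.0, 3.0), 4)
  expect_null(stable_range_oracle(r3))
  expect_error(find_stable_range(make_curve(r3)), "no stable range")

  # random curves agree with the oracle wherever the oracle finds a run
  set.seed(10)
  for (i in 1:25) {
    r <- round(runif(7, 0.5, 3), 2)
    r[sample(7, sample(0:2, 1))] <- NA
    orc <- stable_range_oracle(r)
    if (is.null(orc)) {
      expect_error(find_stable_range(make_curve(r)), "stable range|too few")
    } else {
      expect_equal(find_stable_range(make_curve(r)), orc, info = paste(r, collapse = ","))
    }
  }
})

test_that("cell E/I ratios recover the plateau and carry phase metadata", {
  ser <- gen_evoked_series(noise_rms = 0, seed = 2)
  cer <- cell_ei_ratio(compute_ratio_curve(ser$pairs), zeitgeber_time = 18)
  expect_equal(cer$value, 0.5, tolerance = 5e-3)
  expect_gte(cer$n_intensities_used, 3)
  expect_equal(cer$phase, "dark")

  # scale invariance: common gain on both traces leaves the ratio unchanged
  scaled <- lapply(ser$pairs, function(p) {
    p$excitatory$samples <- 3.7 * p$excitatory$samples
    p$inhibitory$samples <- 3.7 * p$inhibitory$samples
    p
  })
  cer2 <- cell_ei_ratio(compute_ratio_curve(scaled), zeitgeber_time = 18)
  expect_equal(cer2$value, cer$value, tolerance = 1e-12)

  # ordering invariance: reversed intensity order, re-sorted, same answer
  cur_rev <- compute_ratio_curve(rev(ser$pairs))
  o <- order(cur_rev$intensities)
  cur_sorted <- cur_rev
  for (f in c("intensities", "e_peaks", "i_peaks", "ratios", "valid", "discard_flags")) {
    cur_sorted[[f]] <- cur_rev[[f]][o]
  }
  expect_equal(find_stable_range(cur_sorted),
               find_stable_range(compute_ratio_curve(ser$pairs)))
})

test_that("phase pooling maps only the four sampled timepoints", {
  cells <- data.frame(value = c(0.5, 0.4, 0.35, 0.45),
                      zeitgeber_time = c(0, 18, 6, 12))
  pooled <- pool_phase(cells)
  expect_equal(pooled$phase, c("dark", "dark", "light", "light"))
  expect_error(pool_phase(data.frame(value = 1, zeitgeber_time = 3)),
               "not one of the pooled timepoints")
})
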