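test_that("RMS noise estimation excludes events and handles degenerate traces", {
  g <- gen_mini_sweep(rate = 0, duration = 60, noise_rms = 2, seed = 1)
  est <- estimate_rms_noise(g$sweep)
  # oracle: the generator's trace IS the noise array here
  expect_equal(est, sd(g$sweep$samples), tolerance = 0.03)
  expect_equal(est, 2, tolerance = 0.05)

  zero <- sweep_recording(numeric(12 * 10000), 10000)
  expect_equal(estimate_rms_noise(zero), 0)

  # 1 Hz events of 30 pA on sigma = 1.5 noise: iteration strips the events
  ev <- make_event_sweep(times = seq(0.5, 59.5, by = 1), amplitude = 30,
                         noise_rms = 1.5, seed = 2)
  expect_equal(estimate_rms_noise(ev), 1.5, tolerance = 0.075)

  expect_error(estimate_rms_noise(sweep_recording(rnorm(500), 100)), "10 s")
  sat <- sweep_recording(rep(c(-100, 100), 60000), 10000)
  expect_error(estimate_rms_noise(sat), "saturated")
})

test_that("QC thresholds are strict and class-specific", {
  expect_true(qc_cell(1.9, "mEPSC"))
  expect_false(qc_cell(2.0, "mEPSC"))
  expect_true(qc_cell(3.9, "mIPSC"))
  expect_false(qc_cell(4.0, "mIPSC"))
  expect_error(qc_cell(-1, "mEPSC"))
})

test_that("well-separated injected events are each detected with accurate onsets", {
  times <- seq(1, 55, length.out = 10)
  rec <- make_event_sweep(times, amplitude = 20, noise_rms = 1.5, seed = 3)
  ev <- detect_events(rec, 1.5)
  expect_equal(nrow(ev), 10)
  expect_lt(max(abs(ev$onset_time - times)), 0.002)
  expect_equal(mean(ev$amplitude), 20, tolerance = 0.1)
  expect_true(all(ev$peak_time > ev$onset_time))
  expect_true(all(diff(ev$onset_time) > 0))
})

test_that("detection respects the threshold and ignores sub-threshold events", {
  # amplitude below 3x RMS: events go essentially undetected (any residual
  # crossings stay at the false-positive level, far below the 0.167 Hz
  # injected rate)
  n_det <- sum(vapply(1:5, function(s) {
    rec <- make_event_sweep(seq(1, 55, length.out = 10), amplitude = 4,
                            noise_rms = 2, seed = s)
    nrow(detect_events(rec, 2))
  }, numeric(1)))
  expect_lt(n_det / (5 * 60), 0.05)

  # monotone in the threshold multiplier
  rec2 <- gen_mini_sweep(rate = 3, duration = 30, seed = 5)$sweep
  rms <- estimate_rms_noise(rec2)
  n3 <- nrow(detect_events(rec2, rms, threshold_mult = 3))
  n5 <- nrow(detect_events(rec2, rms, threshold_mult = 5))
  expect_lte(n5, n3)

  # invariant to a DC offset
  recA <- make_event_sweep(c(2, 10, 20), amplitude = 25, seed = 6, dc = 0)
  recB <- sweep_recording(recA$samples + 150, recA$sampling_rate,
                          meta = recA$meta)
  evA <- detect_events(recA, 1.5)
  evB <- detect_events(recB, 1.5)
  expect_equal(evA$onset_time, evB$onset_time)
  expect_equal(evA$amplitude, evB$amplitude, tolerance = 1e-10)
})

test_that("event selection applies rise-time limits and chronological truncation", {
  ev <- data.frame(onset_time = seq(0, 39.9, by = 0.1),
                   peak_time = seq(0, 39.9, by = 0.1) + 0.002,
                   amplitude = rep(20, 400),
                   rise_time = rep(1, 400),
                   preceding_interval = c(NA, rep(0.1, 399)))
  sel <- select_events(ev, "mEPSC", n_target = 300)
  expect_equal(nrow(sel), 300)
  expect_equal(sel$onset_time, ev$onset_time[1:300])
  expect_false(attr(sel, "shortfall"))

  # boundary: rise time exactly at the limit is excluded (strict <)
  ev$rise_time[5] <- 3.0
  sel2 <- select_events(ev, "mEPSC", n_target = 300)
  expect_false(ev$onset_time[5] %in% sel2$onset_time)
  ev$rise_time[5] <- 4.9
  sel3 <- select_events(ev, "mIPSC", n_target = 300)
  expect_true(ev$onset_time[5] %in% sel3$onset_time)

  ev$rise_time[5] <- 1
  few <- ev[1:150, ]
  sel4 <- select_events(few, "mEPSC", n_target = 300)
  expect_equal(nrow(sel4), 150)
  expect_true(attr(sel4, "shortfall"))
})

test_that("cell summaries report span-based frequency and mean amplitude", {
  times <- seq(0, 100, length.out = 300)   # 300 events spanning exactly 100 s
  rec <- make_event_sweep(times, amplitude = 20, noise_rms = 1, duration = 105,
                          seed = 7)
  ev <- data.frame(onset_time = times, peak_time = times + 0.002,
                   amplitude = rnorm(300, 20, 1), rise_time = 1,
                   preceding_interval = c(NA, diff(times)))
  s <- summarize_cell(ev, rec, rms_noise = 1)
  expect_equal(s$frequency, 2.99)
  expect_equal(s$mean_amplitude, mean(ev$amplitude))
  expect_equal(s$n_events_used, 300)
  expect_true(s$qc_pass)

  expect_error(summarize_cell(ev[1, , drop = FALSE], rec), "insufficient")
})

test_that("averaged waveforms use only isolated events and recover the kernel", {
  # two events 5 ms apart within a 50 ms window: neither is used
  close_ev <- data.frame(onset_time = c(1.000, 1.005),
                         peak_time = c(1.002, 1.007),
                         amplitude = c(20, 20), rise_time = 1,
                         preceding_interval = c(NA, 0.005))
  rec <- make_event_sweep(c(1.000, 1.005), duration = 12, seed = 8)
  expect_error(average_nonoverlapping(close_ev, rec), "non-overlapping")
  expect_error(average_nonoverlapping(close_ev[0, ], rec), "no events")

  # isolated events: average peak matches the kernel amplitude within noise
  times <- seq(1, 55, length.out = 25)
  rec2 <- make_event_sweep(times, amplitude = 20, noise_rms = 1, seed = 9)
  ev2 <- detect_events(rec2, 1)
  avg <- average_nonoverlapping(ev2, rec2, window = 50)
  expect_equal(attr(avg, "n_averaged"), 25)
  expect_equal(max(avg), 20, tolerance = 1 / sqrt(25) * 3 / 20 + 0.03)
})

test_that("summaries recover generator ground truth across seeds", {
  fr <- amp <- numeric(8)
  for (s in 1:8) {
    g <- gen_mini_sweep(rate = 3, amp_mean = 25, duration = 60, seed = s)
    cs <- analyze_mini_cell(g$sweep, "mEPSC")
    fr[s] <- cs$frequency; amp[s] <- cs$mean_amplitude
  }
  expect_equal(mean(fr), 3, tolerance = 0.1)
  expect_equal(mean(amp), 25, tolerance = 0.05)
})
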