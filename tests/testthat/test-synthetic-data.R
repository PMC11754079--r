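test_that("PSC kernel is peak-normalized and matches quadrature", {
  k <- psc_kernel(20, 0.5, 5, 10000)
  expect_equal(max(k), 20, tolerance = 1e-3)
  expect_gte(length(k), 5 * 5 / 1000 * 10000)
  expect_true(all(psc_kernel(0, 0.5, 5, 10000) == 0))
  expect_error(psc_kernel(10, 5, 5, 10000), "decay_tau")

  # closed-form integral vs numeric quadrature of the closed form (100x grid)
  f <- function(t_ms) 20 / eiosc:::psc_peak_factor(0.5, 5) *
    (exp(-t_ms / 5) - exp(-t_ms / 0.5))
  quad <- stats::integrate(f, 0, 500, rel.tol = 1e-10)$value / 1000
  expect_equal(eiosc:::psc_kernel_integral(20, 0.5, 5), quad, tolerance = 1e-3)

  # discrete kernel sum converges to quadrature over the same support
  k_hi <- psc_kernel(20, 0.5, 5, 1e6)
  support_ms <- (length(k_hi) - 1) / 1e6 * 1000
  quad_support <- stats::integrate(f, 0, support_ms, rel.tol = 1e-10)$value / 1000
  expect_equal(sum(k_hi) / 1e6, quad_support, tolerance = 1e-3)
})

test_that("mini-sweep generator is seeded, Poisson-calibrated, and honest at rate 0", {
  g1 <- gen_mini_sweep(rate = 2, duration = 20, seed = 7)
  g2 <- gen_mini_sweep(rate = 2, duration = 20, seed = 7)
  expect_identical(g1$sweep$samples, g2$sweep$samples)
  expect_identical(g1$truth$event_times, g2$truth$event_times)

  g0 <- gen_mini_sweep(rate = 0, duration = 20, noise_rms = 2, seed = 8)
  expect_length(g0$truth$event_times, 0)
  expect_equal(sd(g0$sweep$samples), 2, tolerance = 0.1)

  expect_true(all(diff(g1$truth$event_times) > 0) || length(g1$truth$event_times) < 2)
  expect_true(all(g1$truth$event_amplitudes > 0))

  # mean event count over 50 seeds matches the Poisson mean within 3 SD
  counts <- vapply(1:50, function(s) {
    length(gen_mini_sweep(rate = 2, duration = 60, seed = s)$truth$event_times)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 120), 3 * sqrt(120))
  # and the amplitude law has the configured mean
  amps <- unlist(lapply(1:20, function(s)
    gen_mini_sweep(rate = 2, duration = 60, seed = s)$truth$event_amplitudes))
  expect_equal(mean(amps), 15, tolerance = 0.05)
})

test_that("sIPSC generator enforces duration, exposes drift, and states true charge", {
  expect_error(gen_sipsc_sweep(duration = 170), "180")

  g0 <- gen_sipsc_sweep(rate = 0, noise_rms = 0, duration = 200, seed = 3)
  expect_equal(g0$sweep$samples, g0$truth$drift, tolerance = 1e-12)
  expect_equal(g0$truth$total_charge, 0)

  g <- gen_sipsc_sweep(duration = 200, seed = 4)
  # ground-truth charge equals quadrature of each kernel's closed form
  f <- function(t_ms, a) a / eiosc:::psc_peak_factor(1, 15) *
    (exp(-t_ms / 15) - exp(-t_ms / 1))
  quad <- sum(vapply(g$truth$event_amplitudes, function(a)
    stats::integrate(f, 0, 1500, a = a, rel.tol = 1e-9)$value / 1000, numeric(1)))
  expect_equal(g$truth$total_charge, quad, tolerance = 1e-6)
  expect_equal(g$truth$true_unit_charge, g$truth$total_charge / 200)
})

test_that("evoked generator attains the configured ratio with a stable plateau", {
  ser <- gen_evoked_series(e_max = 200, i_max = 400, noise_rms = 0, seed = 1)
  expect_equal(ser$truth$true_ratio, 0.5)
  cur <- compute_ratio_curve(ser$pairs)
  post <- cur$ratios[ser$truth$stable_onset_index:length(cur$ratios)]
  expect_equal(post, rep(0.5, length(post)), tolerance = 5e-3)

  s1 <- gen_evoked_series(seed = 5)
  s2 <- gen_evoked_series(seed = 5)
  expect_identical(s1$pairs[[3]]$excitatory$samples, s2$pairs[[3]]$excitatory$samples)

  expect_error(gen_evoked_series(intensities = c(10, 20, 15, 30)), "increasing")
  expect_error(gen_evoked_series(intensities = c(10, 20, 30)), "4 intensities")
})

test_that("sleep truth follows the configured chain and the EEG carries state bands", {
  # identity transition matrices freeze the chain in its initial state
  p <- sleep_defaults()
  p$transition_light <- p$transition_dark <- diag(3)
  truth <- gen_sleep_truth(hours = 0.5, seed = 2, params = p)
  expect_true(all(truth$state_sequence == "WAKE"))

  t1 <- gen_sleep_truth(hours = 1, seed = 3)
  t2 <- gen_sleep_truth(hours = 1, seed = 3)
  expect_identical(t1$state_sequence, t2$state_sequence)

  ps <- gen_polysomnography(t1, seed = 4)
  sp <- state_spectra(ps$psg, ps$hypnogram)
  if (sp$epochs_used["NREM"] > 0) {
    peak_bin <- sp$frequencies[which.max(sp$relative_power["NREM", ])]
    expect_true(peak_bin >= 0.5 && peak_bin <= 4)
  }
  g1 <- gen_polysomnography(t1, seed = 9)
  g2 <- gen_polysomnography(t1, seed = 9)
  expect_identical(g1$psg$eeg, g2$psg$eeg)
})

test_that("imaging generator yields exact Fourier recovery at zero noise", {
  truth <- gen_imaging_truth(noise_sd = 0)
  st <- gen_imaging_stack(truth, seed = 1)
  fm <- fourier_response(st$contra)
  expect_equal(fm$magnitude, truth$contra_amp, tolerance = 1e-10)
  dphi <- ((fm$phase - truth$phase_map + pi) %% (2 * pi)) - pi
  expect_lt(max(abs(dphi)), 0.05)

  # fully monocular truth drives the downstream ODI to 1
  tm <- gen_imaging_truth(ipsi_peak = 0, ipsi_base = 0, noise_sd = 0)
  stm <- gen_imaging_stack(tm, seed = 2)
  cmap <- smooth_map(fourier_response(stm$contra))
  imap <- smooth_map(fourier_response(stm$ipsi))
  odi <- compute_odi(cmap, imap, binocular_roi(imap))
  expect_equal(odi$odi, 1)

  a <- gen_imaging_stack(truth, seed = 6)$ipsi
  b <- gen_imaging_stack(truth, seed = 6)$ipsi
  expect_identical(a$frames, b$frames)
})
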