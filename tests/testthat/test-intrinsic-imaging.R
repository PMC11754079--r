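test_that("single-bin DFT recovers cosine amplitude and phase exactly", {
  truth <- gen_imaging_truth(height = 12, width = 12, noise_sd = 0)
  st <- gen_imaging_stack(truth, f_stim = 0.05, frame_rate = 5, n_cycles = 4,
                          seed = 1)
  fm <- fourier_response(st$contra)
  expect_lt(max(abs(fm$magnitude - truth$contra_amp)), 1e-6)
  dphi <- ((fm$phase - truth$phase_map + pi) %% (2 * pi)) - pi
  expect_lt(max(abs(dphi)), 0.05)

  zero <- image_stack(array(0, c(8, 8, 250)), frame_rate = 5,
                      stimulus_frequency = 0.05)
  expect_true(all(fourier_response(zero)$magnitude == 0))
})

test_that("Gaussian smoothing conserves mass and reduces noise variance", {
  mk_map <- function(mag) structure(list(magnitude = mag, phase = mag * 0,
                                         eye = "ipsi", stimulus_extent = "full_field",
                                         smoothed = FALSE), class = "response_map")
  const <- mk_map(matrix(3.2, 10, 10))
  expect_equal(smooth_map(const)$magnitude, const$magnitude, tolerance = 1e-12)

  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  sm <- smooth_map(mk_map(imp))$magnitude
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_equal(which.max(sm), 61L)  # mass stays centered

  set.seed(4)
  noisy <- mk_map(matrix(rnorm(400), 20, 20))
  expect_lt(var(as.vector(smooth_map(noisy)$magnitude)),
            var(as.vector(noisy$magnitude)))

  expect_error(smooth_map(mk_map(matrix(0, 3, 3))), "smaller")
})

test_that("ROI selection keeps the top fraction with deterministic ties", {
  mk_map <- function(mag) structure(list(magnitude = mag, phase = mag * 0,
                                         eye = "ipsi", stimulus_extent = "binocular_field",
                                         smoothed = TRUE), class = "response_map")
  m <- mk_map(matrix(1:10, 2, 5))     # values 1..10
  roi <- binocular_roi(m, 0.7)
  expect_equal(sum(roi), 7)
  expect_setequal(m$magnitude[roi], 4:10)

  # constant map: ties resolve in row-major order
  cm <- mk_map(matrix(1, 3, 4))
  roi2 <- binocular_roi(cm, 0.5)
  expect_equal(sum(roi2), 6)
  rm_positions <- which(t(roi2))     # row-major scan
  expect_equal(rm_positions, 1:6)

  expect_true(all(binocular_roi(m, 1.0)))
  expect_error(binocular_roi(m, 0), "fraction")
})

test_that("ODI closed forms, antisymmetry, and scale invariance hold", {
  mk_map <- function(mag) structure(list(magnitude = mag, phase = mag * 0,
                                         eye = "contra", stimulus_extent = "binocular_field",
                                         smoothed = TRUE), class = "response_map")
  c3 <- mk_map(matrix(3, 6, 6)); i1 <- mk_map(matrix(1, 6, 6))
  roi <- matrix(TRUE, 6, 6)
  expect_equal(compute_odi(c3, c3, roi)$odi, 0)
  expect_equal(compute_odi(c3, mk_map(matrix(0, 6, 6)), roi)$odi, 1)
  expect_equal(compute_odi(c3, i1, roi)$odi, 0.5)
  # swapping the eyes negates the ODI exactly
  set.seed(5)
  a <- mk_map(matrix(runif(36, 0.5, 2), 6, 6))
  b <- mk_map(matrix(runif(36, 0.5, 2), 6, 6))
  expect_equal(compute_odi(a, b, roi)$odi, -compute_odi(b, a, roi)$odi)
  # common gain leaves it unchanged
  a2 <- a; a2$magnitude <- 7 * a$magnitude
  b2 <- b; b2$magnitude <- 7 * b$magnitude
  expect_equal(compute_odi(a2, b2, roi)$odi, compute_odi(a, b, roi)$odi,
               tolerance = 1e-12)

  expect_error(compute_odi(mk_map(matrix(0, 6, 6)), mk_map(matrix(0, 6, 6)), roi),
               "empty ROI")
  expect_error(compute_odi(a, mk_map(matrix(1, 3, 3)), roi), "co-registered")
})

test_that("responsive area counts an activated patch against the noise floor", {
  # 100-pixel active patch (10x10, feathered 1-px border) at 10x the
  # smoothed-map noise SD in a 48x48 field; mean count over 10 draws is
  # compared against the patch support
  h <- 48; sigma_f <- 0.02
  mk <- function(mag) structure(list(magnitude = mag, phase = mag * 0,
                                     eye = "contra", stimulus_extent = "full_field",
                                     smoothed = FALSE), class = "response_map")
  counts <- vapply(1:10, function(s) {
    set.seed(s)
    noise <- matrix(Mod(complex(real = rnorm(h * h, 0, sigma_f),
                                imaginary = rnorm(h * h, 0, sigma_f))), h, h)
    sd_sm <- sd(as.vector(smooth_map(mk(noise))$magnitude))
    amp <- 10 * sd_sm
    patch <- matrix(0, h, h)
    patch[20:29, 20:29] <- 0.5 * amp
    patch[21:28, 21:28] <- amp
    responsive_area(smooth_map(mk(noise + patch)))
  }, numeric(1))
  expect_gte(mean(counts), 90)
  expect_lte(mean(counts), 110)
  sm <- {
    set.seed(1)
    noise <- matrix(Mod(complex(real = rnorm(h * h, 0, sigma_f),
                                imaginary = rnorm(h * h, 0, sigma_f))), h, h)
    patch <- matrix(0, h, h); patch[20:29, 20:29] <- 1
    smooth_map(mk(noise + patch))
  }
  count <- responsive_area(sm)

  expect_equal(responsive_area(mk(matrix(0, h, h))), 0)

  # doubling every amplitude cannot reduce the count
  dbl <- sm; dbl$magnitude <- 2 * sm$magnitude
  expect_gte(responsive_area(dbl), count)
})

test_that("the full pipeline recovers the generator's true ODI", {
  for (s in 1:2) {
    truth <- gen_imaging_truth()
    st <- gen_imaging_stack(truth, seed = s)
    odi <- analyze_ocular_dominance(st$contra, st$ipsi)
    expect_lt(abs(odi$odi - truth$true_odi), 0.05)
  }
})
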