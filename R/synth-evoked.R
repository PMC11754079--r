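#' Generate a synthetic evoked input-output series with known E/I ratio
#'
#' Emulates the paired-holding-potential protocol: at each stimulation
#' intensity one sweep is recorded at -55 mV (excitatory response, downward)
#' and one at +10 mV (inhibitory response, upward). True peak amplitudes follow
#' saturating Hill curves that share one half-saturation intensity, so the true
#' per-intensity ratio equals `e_max / i_max` wherever no jitter is applied and
#' a stable-ratio plateau exists by construction. `threshold_jitter` applies
#' multiplicative log-normal jitter to the excitatory peak at intensities below
#' the half-saturation point, creating an unstable low-intensity region that
#' exercises the stable-range search.
#'
#' Each trace contains a brief biphasic stimulus artifact at `stim_onset`, a
#' monosynaptic first peak, and a smaller polysynaptic second peak ~12 ms
#' later, so the first-peak rule is exercised on every sweep.
#'
#' @param intensities Increasing stimulus levels (at least 4).
#' @param e_max,i_max Saturated excitatory/inhibitory peak amplitudes, pA.
#' @param half_saturation Shared Hill half-saturation intensity.
#' @param hill Hill coefficient of the recruitment curves.
#' @param threshold_jitter SD of log-normal jitter applied below
#'   `half_saturation` (0 disables).
#' @param noise_rms Gaussian trace noise, pA.
#' @param polysynaptic_frac Second-peak amplitude as a fraction of the first.
#' @param sampling_rate Hz.
#' @param seed Integer seed.
#' @return List with `pairs` (one element per intensity: `intensity`,
#'   `excitatory` and `inhibitory` [sweep_recording]s, `stim_onset` s) and
#'   `truth` (`intensities`, `true_e_peak`, `true_i_peak`, `true_ratio`,
#'   `stable_onset_index`, 1-based).
#' @export
gen_evoked_series <- function(intensities = seq(10, 80, by = 10),
                              e_max = 200, i_max = 400, half_saturation = 25,
                              hill = 3, threshold_jitter = 0, noise_rms = 5,
                              polysynaptic_frac = 0.35,
                              sampling_rate = 10000, seed = 1) {
  if (length(intensities) < 4) stop("at least 4 intensities required")
  if (any(diff(intensities) <= 0)) stop("intensities must be strictly increasing")
  set.seed(as.integer(seed))

  hillf <- function(I, vmax) vmax * I^hill / (I^hill + half_saturation^hill)
  e_peak <- hillf(intensities, e_max)
  i_peak <- hillf(intensities, i_max)
  below <- intensities < half_saturation
  if (threshold_jitter > 0 && any(below)) {
    e_peak[below] <- e_peak[below] * exp(stats::rnorm(sum(below), 0, threshold_jitter))
  }
  stable_onset <- which(!below)[1]

  duration <- 0.08
  stim_onset <- 0.02
  n_samp <- round(duration * sampling_rate)
  on_idx <- round(stim_onset * sampling_rate) + 1L

  add_kernel <- function(x, latency_s, amp, rise, decay) {
    k <- psc_kernel(amp, rise, decay, sampling_rate)
    i0 <- on_idx + round(latency_s * sampling_rate)
    i1 <- min(i0 + length(k) - 1L, n_samp)
    x[i0:i1] <- x[i0:i1] + k[seq_len(i1 - i0 + 1L)]
    x
  }
  make_trace <- function(first_amp, rise, decay, latency, sign) {
    x <- numeric(n_samp)
    # biphasic stimulus artifact, 0.3 ms
    art <- on_idx:(on_idx + round(0.0003 * sampling_rate))
    x[art] <- 2000 * rep_len(c(1, -1), length(art))
    x <- add_kernel(x, latency, first_amp, rise, decay)
    x <- add_kernel(x, latency + 0.012, polysynaptic_frac * first_amp, rise, decay)
    sign * x + stats::rnorm(n_samp, 0, noise_rms)
  }

  pairs <- lapply(seq_along(intensities), function(j) {
    exc <- sweep_recording(
      make_trace(e_peak[j], rise = 1, decay = 8, latency = 0.002, sign = -1),
      sampling_rate, holding_potential = -55, meta = list(polarity = "inward"))
    inh <- sweep_recording(
      make_trace(i_peak[j], rise = 1.5, decay = 15, latency = 0.0025, sign = +1),
      sampling_rate, holding_potential = 10, meta = list(polarity = "outward"))
    list(intensity = intensities[j], excitatory = exc, inhibitory = inh,
         stim_onset = stim_onset)
  })

  truth <- list(intensities = intensities, true_e_peak = e_peak,
                true_i_peak = i_peak, true_ratio = e_max / i_max,
                stable_onset_index = stable_onset)
  list(pairs = pairs, truth = truth)
}
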