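#' Default sleep-state transition matrices and spectral parameters
#'
#' Per-4-s-epoch Markov transition matrices for the light and dark phases
#' (rows/columns ordered WAKE, NREM, REM), per-state EEG band weights (uV RMS
#' per band-limited noise component) and per-state EMG RMS levels (uV). The
#' defaults produce nocturnal-rodent behaviour: mostly asleep in the light
#' phase, mostly awake in the dark phase, delta-dominated NREM EEG,
#' theta-dominated REM EEG, and high EMG tone only in wake.
#'
#' @return Named list with `transition_light`, `transition_dark`,
#'   `band_weights`, `bands`, `emg_level`.
#' @export
sleep_defaults <- function() {
  tl <- rbind(WAKE = c(0.920, 0.075, 0.005),
              NREM = c(0.055, 0.900, 0.045),
              REM  = c(0.120, 0.060, 0.820))
  td <- rbind(WAKE = c(0.975, 0.024, 0.001),
              NREM = c(0.080, 0.885, 0.035),
              REM  = c(0.150, 0.050, 0.800))
  colnames(tl) <- colnames(td) <- SLEEP_STATES
  list(
    transition_light = tl,
    transition_dark = td,
    bands = list(delta = c(0.5, 4), theta = c(5, 9), gamma = c(30, 80),
                 broad = c(0.5, 80)),
    band_weights = rbind(WAKE = c(delta = 15, theta = 25, gamma = 15, broad = 10),
                         NREM = c(delta = 60, theta = 15, gamma = 5,  broad = 10),
                         REM  = c(delta = 10, theta = 45, gamma = 8,  broad = 8)),
    emg_level = c(WAKE = 40, NREM = 8, REM = 4)
  )
}

#' Simulate a ground-truth sleep-state sequence
#'
#' Draws per-epoch states from the phase-appropriate Markov chain (light phase
#' ZT0-12, dark phase ZT12-24). The returned object carries everything the
#' signal generator and the validation oracles need: the state sequence, both
#' transition matrices, band parameters and EMG levels.
#'
#' @param hours Recording span in hours (72 = the 3-day home-cage protocol).
#' @param start_zt Zeitgeber time of the first epoch.
#' @param seed Integer seed.
#' @param params Parameter list as from [sleep_defaults()].
#' @param epoch_length Epoch duration, s.
#' @return Object of class `sleep_truth`: `state_sequence`, `epoch_length`,
#'   `start_zt`, plus all generator parameters.
#' @export
gen_sleep_truth <- function(hours = 72, start_zt = 0, seed = 1,
                            params = sleep_defaults(), epoch_length = 4) {
  set.seed(as.integer(seed))
  n_epochs <- round(hours * 3600 / epoch_length)
  zt <- (start_zt + (seq_len(n_epochs) - 1L) * epoch_length / 3600) %% 24
  light <- zt < 12
  states <- integer(n_epochs)
  states[1] <- if (light[1]) 1L else 1L  # start awake
  for (i in 2:n_epochs) {
    P <- if (light[i]) params$transition_light else params$transition_dark
    states[i] <- sample.int(3L, 1L, prob = P[states[i - 1], ])
  }
  structure(list(state_sequence = SLEEP_STATES[states],
                 epoch_length = epoch_length, start_zt = start_zt,
                 params = params),
            class = "sleep_truth")
}

# Stationary distribution of a row-stochastic matrix (left eigenvector).
markov_stationary <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- v / sum(v)
  stats::setNames(v, colnames(P))
}

# Band-limited Gaussian noise of unit RMS via FFT masking.
band_noise <- function(n, sampling_rate, band) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) * sampling_rate / n
  f <- pmin(f, sampling_rate - f)            # two-sided frequency axis
  keep <- f >= band[1] & f <= band[2]
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  r <- sqrt(mean(y^2))
  if (r == 0) return(numeric(n))
  y / r
}

#' Synthesize EEG/EMG signals for a ground-truth state sequence
#'
#' Per epoch, the EEG is a sum of band-limited Gaussian noise components
#' (delta, theta, gamma, broadband) weighted by the state's configured uV RMS
#' levels; the EMG is white noise at the state's RMS level. The returned
#' hypnogram is the ground truth itself.
#'
#' @param truth A `sleep_truth` from [gen_sleep_truth()].
#' @param seed Integer seed (signal noise; independent of the state sequence).
#' @param sampling_rate Hz (500 nominal).
#' @param animal_id,genotype Metadata for the recording.
#' @return List with `psg` (a [psg_recording]) and `hypnogram` (a [hypnogram]).
#' @export
gen_polysomnography <- function(truth, seed = 1, sampling_rate = 500,
                                animal_id = "synthetic", genotype = "WT") {
  stopifnot(inherits(truth, "sleep_truth"))
  set.seed(as.integer(seed))
  p <- truth$params
  n_per_epoch <- round(truth$epoch_length * sampling_rate)
  n_epochs <- length(truth$state_sequence)
  eeg <- numeric(n_epochs * n_per_epoch)
  emg <- numeric(n_epochs * n_per_epoch)
  band_names <- names(p$bands)
  for (i in seq_len(n_epochs)) {
    st <- truth$state_sequence[i]
    w <- p$band_weights[st, ]
    seg <- numeric(n_per_epoch)
    for (b in band_names) {
      seg <- seg + w[[b]] * band_noise(n_per_epoch, sampling_rate, p$bands[[b]])
    }
    idx <- ((i - 1L) * n_per_epoch + 1L):(i * n_per_epoch)
    eeg[idx] <- seg
    emg[idx] <- stats::rnorm(n_per_epoch, 0, p$emg_level[[st]])
  }
  psg <- psg_recording(eeg, emg, sampling_rate = sampling_rate,
                       start_zeitgeber_time = truth$start_zt,
                       animal_id = animal_id, genotype = genotype)
  hyp <- hypnogram(truth$state_sequence, epoch_length = truth$epoch_length,
                   start_zeitgeber_time = truth$start_zt)
  list(psg = psg, hypnogram = hyp)
}
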