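#' Construct a voltage-clamp sweep recording
#'
#' A `sweep_recording` holds one continuous voltage-clamp current trace together
#' with its acquisition parameters and cell/condition metadata. Currents are
#' stored in pA for miniature and evoked sweeps; nA is permitted for spontaneous
#' IPSC records (set `meta$units = "nA"`).
#'
#' @param samples Numeric vector of current samples. All values must be finite.
#' @param sampling_rate Sampling rate in Hz (must be positive; recordings are
#'   nominally digitized at 10 kHz after 2 kHz filtering).
#' @param holding_potential Holding potential in mV (e.g. -70 for minis, -55 /
#'   +10 for the paired evoked protocol).
#' @param meta Named list of metadata. Recognised fields: `cell_id`,
#'   `animal_id`, `genotype`, `zeitgeber_time` (hours, in \[0, 24)), `circuit`
#'   (`"L2/3-2/3"` or `"L4-2/3"`), `drug` (`"vehicle"`, `"WIN"`, `"SR"`,
#'   `"none"`), `polarity` (`"inward"` or `"outward"`; stored, never inferred
#'   from the data), and `units` (`"pA"` default, `"nA"` allowed).
#' @return An object of class `sweep_recording` with fields `samples`,
#'   `sampling_rate`, `holding_potential`, `duration` (s) and `meta`.
#' @export
sweep_recording <- function(samples, sampling_rate, holding_potential = NA_real_,
                            meta = list()) {
  samples <- as.numeric(samples)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  if (any(!is.finite(samples))) {
    stop(sprintf("non-finite samples in sweep '%s'",
                 if (is.null(meta$cell_id)) "<unnamed>" else meta$cell_id))
  }
  if (!is.null(meta$zeitgeber_time)) {
    zt <- meta$zeitgeber_time
    if (!is.finite(zt) || zt < 0 || zt >= 24) stop("zeitgeber_time must lie in [0, 24)")
  }
  if (is.null(meta$units)) meta$units <- "pA"
  if (is.null(meta$polarity)) meta$polarity <- "inward"
  structure(list(
    samples = samples,
    sampling_rate = as.numeric(sampling_rate),
    holding_potential = as.numeric(holding_potential),
    duration = length(samples) / sampling_rate,
    meta = meta
  ), class = "sweep_recording")
}

#' @export
print.sweep_recording <- function(x, ...) {
  cat(sprintf("<sweep_recording> %d samples @ %g Hz (%.3f s), Vhold %g mV, units %s\n",
              length(x$samples), x$sampling_rate, x$duration,
              x$holding_potential, x$meta$units))
  invisible(x)
}

#' Construct a polysomnography recording
#'
#' Paired EEG/EMG series from chronic home-cage telemetry, nominally sampled at
#' 500 Hz. The sampling rate must exceed 160 Hz so that the 0.5-80 Hz analysis
#' range is representable.
#'
#' @param eeg,emg Numeric vectors in microvolts, equal length.
#' @param sampling_rate Hz.
#' @param start_zeitgeber_time Zeitgeber time (h) of the first sample.
#' @param animal_id,genotype Identification metadata.
#' @param exclude_spectral Logical; animals with atypical electrode placement
#'   can be flagged for exclusion from spectral (but not architecture) analysis.
#' @return Object of class `psg_recording`.
#' @export
psg_recording <- function(eeg, emg, sampling_rate = 500, start_zeitgeber_time = 0,
                          animal_id = NA_character_, genotype = NA_character_,
                          exclude_spectral = FALSE) {
  eeg <- as.numeric(eeg); emg <- as.numeric(emg)
  if (length(eeg) != length(emg)) stop("eeg and emg must have equal length")
  if (sampling_rate <= 2 * 80) stop("sampling_rate must exceed 160 Hz (2 x 80 Hz)")
  structure(list(
    eeg = eeg, emg = emg, sampling_rate = as.numeric(sampling_rate),
    start_zeitgeber_time = start_zeitgeber_time,
    animal_id = animal_id, genotype = genotype,
    exclude_spectral = isTRUE(exclude_spectral)
  ), class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("<psg_recording> %.1f h @ %g Hz, animal %s\n",
              length(x$eeg) / x$sampling_rate / 3600, x$sampling_rate, x$animal_id))
  invisible(x)
}

#' Arousal-state labels accepted in hypnograms
#' @export
SLEEP_STATES <- c("WAKE", "NREM", "REM")

#' Construct a hypnogram
#'
#' Ordered per-epoch arousal-state labels over `WAKE`, `NREM`, `REM`, scored in
#' 4-s epochs.
#'
#' @param labels Character vector of state labels.
#' @param epoch_length Epoch duration in seconds (4 by convention).
#' @param start_zeitgeber_time Zeitgeber time (h) of the first epoch.
#' @return Object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_length = 4, start_zeitgeber_time = 0) {
  labels <- as.character(labels)
  if (length(labels) == 0) stop("hypnogram labels must be non-empty")
  bad <- setdiff(unique(labels), SLEEP_STATES)
  if (length(bad)) stop(sprintf("unknown state label(s): %s", paste(bad, collapse = ", ")))
  structure(list(labels = labels, epoch_length = epoch_length,
                 start_zeitgeber_time = start_zeitgeber_time),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs x %g s (%.1f h), start ZT%g\n",
              length(x$labels), x$epoch_length,
              length(x$labels) * x$epoch_length / 3600, x$start_zeitgeber_time))
  print(table(factor(x$labels, levels = SLEEP_STATES)))
  invisible(x)
}

#' Construct an intrinsic-signal image stack
#'
#' A periodic-stimulus imaging record: H x W x T intensity frames acquired while
#' a bar drifts across the visual field at `stimulus_frequency` cycles/s.
#'
#' @param frames Numeric array, dim H x W x T, T covering at least two full
#'   stimulus cycles.
#' @param frame_rate Acquisition rate, Hz; must exceed twice the stimulus
#'   frequency.
#' @param stimulus_frequency Stimulus repetition rate, Hz.
#' @param eye `"contra"` or `"ipsi"` (eye stimulated relative to the imaged
#'   hemisphere).
#' @param stimulus_extent `"full_field"` or `"binocular_field"`.
#' @param direction Drift direction, `"up"` or `"down"`.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_rate, stimulus_frequency,
                        eye = c("contra", "ipsi"),
                        stimulus_extent = c("full_field", "binocular_field"),
                        direction = c("up", "down")) {
  eye <- match.arg(eye)
  stimulus_extent <- match.arg(stimulus_extent)
  direction <- match.arg(direction)
  if (length(dim(frames)) != 3) stop("frames must be an H x W x T array")
  if (frame_rate <= 2 * stimulus_frequency) {
    stop("undersampled: frame_rate must exceed 2 x stimulus_frequency")
  }
  n_cycles <- dim(frames)[3] / frame_rate * stimulus_frequency
  if (n_cycles < 2) stop("stack must cover at least 2 full stimulus cycles")
  structure(list(frames = frames, frame_rate = frame_rate,
                 stimulus_frequency = stimulus_frequency, eye = eye,
                 stimulus_extent = stimulus_extent, direction = direction),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %dx%d px, %d frames @ %g Hz, f_stim %g Hz, %s eye\n",
              d[1], d[2], d[3], x$frame_rate, x$stimulus_frequency, x$eye))
  invisible(x)
}
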