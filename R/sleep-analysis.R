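#' Rule-based arousal-state scorer
#'
#' Stands in for manual scoring on synthetic records: an epoch is WAKE when
#' the EMG RMS exceeds `emg_threshold`; otherwise REM when the EEG
#' theta/delta power ratio exceeds `theta_delta_ratio`; otherwise NREM.
#' Band powers are computed per epoch by Welch periodogram (2-s Hann
#' windows).
#'
#' @param psg A [psg_recording].
#' @param epoch_length Epoch length, s.
#' @param emg_threshold EMG RMS threshold, uV.
#' @param theta_delta_ratio REM decision threshold on theta/delta power.
#' @param delta,theta Band edges, Hz.
#' @return A [hypnogram].
#' @export
score_rule_based <- function(psg, epoch_length = 4, emg_threshold = 20,
                             theta_delta_ratio = 1.5,
                             delta = c(0.5, 4), theta = c(5, 9)) {
  stopifnot(inherits(psg, "psg_recording"))
  fs <- psg$sampling_rate
  n_per <- round(epoch_length * fs)
  n_epochs <- floor(length(psg$eeg) / n_per)
  if (n_epochs < 1) stop("recording shorter than one epoch")
  labels <- character(n_epochs)
  for (i in seq_len(n_epochs)) {
    idx <- ((i - 1L) * n_per + 1L):(i * n_per)
    emg_rms <- sqrt(mean(psg$emg[idx]^2))
    if (emg_rms > emg_threshold) { labels[i] <- "WAKE"; next }
    spec <- welch_psd(psg$eeg[idx], fs, window_s = 2)
    dp <- sum(spec$power[spec$frequency >= delta[1] & spec$frequency < delta[2]])
    tp <- sum(spec$power[spec$frequency >= theta[1] & spec$frequency < theta[2]])
    labels[i] <- if (dp > 0 && tp / dp > theta_delta_ratio) "REM" else "NREM"
  }
  hypnogram(labels, epoch_length = epoch_length,
            start_zeitgeber_time = psg$start_zeitgeber_time)
}

# Welch power spectral density: non-overlapping Hann windows of window_s
# seconds (0.5 Hz resolution at window_s = 2), averaged; returns power per
# frequency bin (one-sided, DC dropped).
welch_psd <- function(x, fs, window_s = 2) {
  n_win <- round(window_s * fs)
  n_seg <- floor(length(x) / n_win)
  if (n_seg < 1) stop("signal shorter than one window")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_win) / (n_win + 1))
  norm <- sum(w^2)
  acc <- NULL
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1L) * n_win + 1L):(s * n_win)]
    X <- stats::fft((seg - mean(seg)) * w)
    p <- Mod(X)^2 / norm
    acc <- if (is.null(acc)) p else acc + p
  }
  acc <- acc / n_seg
  half <- floor(n_win / 2)
  freq <- (seq_len(half)) * fs / n_win
  list(frequency = freq, power = acc[2:(half + 1)])
}

#' Sleep architecture from a hypnogram
#'
#' Percent time in each state per time bin, plus bout counts/durations and
#' state-transition counts over the whole record. A bout is a maximal run of
#' identical labels (minimum one epoch).
#'
#' @param hyp A [hypnogram].
#' @param bin `"1h"` or `"12h"`.
#' @param allow_partial Permit a partial trailing bin (otherwise an error).
#' @return List of class `architecture_summary`: `percent_time` (data.frame
#'   bin x state, percentages summing to 100 per bin), `bouts` (per state:
#'   count, mean duration s), `transitions` (3x3 matrix of ordered
#'   state-pair counts), `bin`, `days_averaged = 1`.
#' @export
architecture <- function(hyp, bin = c("1h", "12h"), allow_partial = FALSE) {
  stopifnot(inherits(hyp, "hypnogram"))
  bin <- match.arg(bin)
  bin_s <- if (bin == "1h") 3600 else 43200
  per_bin <- bin_s / hyp$epoch_length
  n <- length(hyp$labels)
  n_bins <- n / per_bin
  if (n_bins != floor(n_bins)) {
    if (!allow_partial) stop("hypnogram does not span a whole number of bins")
    n_bins <- ceiling(n_bins)
  }
  bin_idx <- ceiling(seq_len(n) / per_bin)
  lab <- factor(hyp$labels, levels = SLEEP_STATES)
  counts <- table(bin = bin_idx, state = lab)
  pct <- sweep(counts, 1, rowSums(counts), "/") * 100
  percent_time <- as.data.frame.matrix(pct)
  percent_time <- cbind(bin = as.integer(rownames(percent_time)),
                        zt_start = (hyp$start_zeitgeber_time +
                                    (as.integer(rownames(percent_time)) - 1) *
                                    bin_s / 3600) %% 24,
                        percent_time)
  rownames(percent_time) <- NULL

  r <- rle(hyp$labels)
  bouts <- do.call(rbind, lapply(SLEEP_STATES, function(s) {
    runs <- r$lengths[r$values == s]
    data.frame(state = s, bout_count = length(runs),
               mean_bout_duration = if (length(runs)) mean(runs) * hyp$epoch_length else NA_real_,
               total_time = sum(runs) * hyp$epoch_length)
  }))

  trans <- matrix(0L, 3, 3, dimnames = list(from = SLEEP_STATES, to = SLEEP_STATES))
  if (length(r$values) > 1) {
    ft <- table(factor(r$values[-length(r$values)], levels = SLEEP_STATES),
                factor(r$values[-1], levels = SLEEP_STATES))
    trans <- trans + as.matrix(ft)
  }

  structure(list(percent_time = percent_time, bouts = bouts,
                 transitions = trans, bin = bin, days_averaged = 1L,
                 epoch_length = hyp$epoch_length),
            class = "architecture_summary")
}

#' Average per-day architecture summaries across recording days
#'
#' Arithmetic mean of percent-time, bout and transition measures across days
#' (each mouse's 3 recording days are averaged before statistics).
#'
#' @param summaries List of `architecture_summary` objects with identical bin
#'   structure.
#' @param n_days Expected number of days.
#' @return An `architecture_summary` with `days_averaged = n_days`.
#' @export
average_days <- function(summaries, n_days = 3) {
  if (length(summaries) != n_days) {
    stop(sprintf("expected %d day summaries, got %d", n_days, length(summaries)))
  }
  bins <- lapply(summaries, function(s) s$percent_time$bin)
  if (!all(vapply(bins[-1], identical, logical(1), bins[[1]]))) {
    stop("mismatched bin structure across days")
  }
  out <- summaries[[1]]
  for (col in SLEEP_STATES) {
    out$percent_time[[col]] <- Reduce(`+`, lapply(summaries, function(s)
      s$percent_time[[col]])) / n_days
  }
  for (col in c("bout_count", "mean_bout_duration", "total_time")) {
    out$bouts[[col]] <- Reduce(`+`, lapply(summaries, function(s)
      s$bouts[[col]])) / n_days
  }
  out$transitions <- Reduce(`+`, lapply(summaries, function(s) s$transitions)) / n_days
  out$days_averaged <- n_days
  out
}

#' State-conditioned normalized EEG power spectra
#'
#' Welch periodograms (2-s Hann windows, 0.5 Hz resolution, no window
#' crossing epoch boundaries) are averaged over all epochs of each arousal
#' state and normalized so the 0.5-80 Hz sum equals 1 per state. A state with
#' no epochs yields an absent (all-NA) profile, not zeros.
#'
#' @param psg A [psg_recording] (sampling rate >= 160 Hz).
#' @param hyp Matching [hypnogram].
#' @param fmax Upper normalization bound, Hz.
#' @return List of class `spectral_profile`: `frequencies` (0.5-Hz grid),
#'   `relative_power` (state x frequency matrix), `epochs_used` per state.
#' @export
state_spectra <- function(psg, hyp, fmax = 80) {
  stopifnot(inherits(psg, "psg_recording"), inherits(hyp, "hypnogram"))
  fs <- psg$sampling_rate
  if (fs < 2 * fmax) stop("sampling rate too low for the requested band")
  n_per <- round(hyp$epoch_length * fs)
  n_epochs <- min(length(hyp$labels), floor(length(psg$eeg) / n_per))
  grid <- seq(0.5, fmax, by = 0.5)
  acc <- matrix(0, 3, length(grid), dimnames = list(SLEEP_STATES, NULL))
  used <- stats::setNames(integer(3), SLEEP_STATES)
  for (i in seq_len(n_epochs)) {
    st <- hyp$labels[i]
    idx <- ((i - 1L) * n_per + 1L):(i * n_per)
    spec <- welch_psd(psg$eeg[idx], fs, window_s = 2)
    keep <- match(grid, spec$frequency)
    if (anyNA(keep)) stop("0.5 Hz grid not resolvable at this sampling rate")
    acc[st, ] <- acc[st, ] + spec$power[keep]
    used[st] <- used[st] + 1L
  }
  rel <- acc
  for (s in SLEEP_STATES) {
    if (used[s] == 0) { rel[s, ] <- NA_real_; next }
    rel[s, ] <- acc[s, ] / sum(acc[s, ])
  }
  structure(list(frequencies = grid, relative_power = rel, epochs_used = used),
            class = "spectral_profile")
}

#' Fractional band power from a normalized spectral profile
#'
#' Sums the relative-power bins whose centers lie in the half-open band
#' `[lo, hi)`; a band whose upper edge reaches the profile ceiling includes
#' it, so complementary bands partition the total power of 1. Conventional
#' rodent bands: delta 0.5-4, theta 5-9, gamma 30-80 Hz.
#'
#' @param profile A `spectral_profile`.
#' @param band Numeric `c(lo, hi)`, Hz, within the profile range.
#' @param state State name.
#' @return Fraction of total power in the band.
#' @export
band_power <- function(profile, band, state = "NREM") {
  stopifnot(inherits(profile, "spectral_profile"), length(band) == 2)
  f <- profile$frequencies
  ceiling_f <- max(f)
  if (band[1] >= band[2] || band[1] < min(f) || band[2] > ceiling_f) {
    stop("band must be a non-empty range within the profile frequencies")
  }
  inb <- f >= band[1] & (f < band[2] | (band[2] >= ceiling_f & f <= ceiling_f))
  if (!any(inb)) stop("empty band")
  sum(profile$relative_power[state, inb])
}
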