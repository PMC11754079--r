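#' Estimate the RMS noise of a voltage-clamp recording
#'
#' RMS of the event-free baseline, computed by iterative exclusion: a slow
#' per-500-ms baseline is removed, then samples beyond 3x the current RMS
#' estimate are excluded and the RMS recomputed until the estimate changes by
#' less than 1%. Synaptic events occupy a small fraction of the record, so the
#' iteration converges onto the noise floor.
#'
#' @param rec A [sweep_recording] of at least 10 s.
#' @return RMS noise in the trace's units.
#' @export
estimate_rms_noise <- function(rec) {
  stopifnot(inherits(rec, "sweep_recording"))
  if (rec$duration < 10) stop("recording must be at least 10 s for noise estimation")
  x <- rec$samples
  rng <- range(x)
  if (rng[1] < rng[2]) {
    at_rail <- sum(x == rng[1]) + sum(x == rng[2])
    if (at_rail >= 0.01 * length(x)) stop("trace saturated: >=1% of samples at rail")
  }
  n_seg <- max(1L, round(0.5 * rec$sampling_rate))
  r <- x - segment_stat(x, n_seg, stats::median)
  rms <- sqrt(mean(r^2))
  if (rms == 0) return(0)
  for (it in 1:25) {
    keep <- abs(r) <= 3 * rms
    new_rms <- sqrt(mean(r[keep]^2))
    if (new_rms == 0) return(0)
    if (abs(new_rms - rms) / rms < 0.01) return(new_rms)
    rms <- new_rms
  }
  rms
}

#' Cell-level quality control on RMS noise
#'
#' Cells are included only when the RMS noise is strictly below 2 pA for mEPSC
#' recordings or 4 pA for mIPSC recordings.
#'
#' @param rms_noise RMS noise, pA.
#' @param event_class `"mEPSC"` or `"mIPSC"`.
#' @return Logical pass flag.
#' @export
qc_cell <- function(rms_noise, event_class = c("mEPSC", "mIPSC")) {
  event_class <- match.arg(event_class)
  stopifnot(rms_noise >= 0)
  rms_noise < if (event_class == "mEPSC") 2 else 4
}

#' Detect miniature PSC events by amplitude threshold
#'
#' The polarity-rectified trace is smoothed with a 0.5-ms boxcar and searched
#' for excursions above `threshold_mult` x RMS noise over the local baseline.
#' Overlapping events are split at local minima (valleys) between peaks.
#' Amplitude is local-baseline-to-peak (baseline = median of the 5 ms preceding
#' onset); rise time is the 10-90% interval. Detection is invariant to a DC
#' offset of the trace.
#'
#' @param rec A [sweep_recording] (QC-passed).
#' @param rms_noise RMS noise from [estimate_rms_noise()].
#' @param polarity `"inward"` or `"outward"`; defaults to the sweep metadata.
#' @param threshold_mult Detection threshold in multiples of RMS noise.
#' @param smooth_ms Boxcar smoothing width, ms.
#' @return `data.frame` with columns `onset_time`, `peak_time` (s),
#'   `amplitude` (positive magnitude), `rise_time` (ms), `preceding_interval`
#'   (s; `NA` for the first event), sorted by onset.
#' @export
detect_events <- function(rec, rms_noise, polarity = NULL,
                          threshold_mult = 3, smooth_ms = 0.5) {
  stopifnot(inherits(rec, "sweep_recording"))
  polarity <- polarity %||% rec$meta$polarity %||% "inward"
  fs <- rec$sampling_rate
  sgn <- if (polarity == "inward") -1 else 1
  y0 <- sgn * rec$samples
  y0 <- y0 - stats::median(y0)
  ys <- boxcar_smooth(y0, round(smooth_ms / 1000 * fs))
  thr <- threshold_mult * rms_noise
  above <- ys > thr

  if (!any(above)) return(empty_events())
  base_w <- max(1L, round(0.005 * fs))    # 5-ms local-baseline window
  smooth_w <- max(1L, round(smooth_ms / 1000 * fs))
  # expected noise SD of the boxcar-smoothed trace; valleys shallower than
  # this scale are ripple, not event boundaries (independent of threshold,
  # so raising the multiplier can only reduce the detection count)
  merge_depth <- 6 * rms_noise / sqrt(smooth_w)

  # candidate peaks: local maxima of the smoothed trace above threshold
  pk <- local_maxima(ys)
  pk <- pk[ys[pk] > thr]
  if (!length(pk)) return(empty_events())
  # single-pass merge of candidates not separated by a real valley: a stack
  # of accepted peaks, each with the valley to its left neighbour
  if (length(pk) > 1) {
    vall <- vapply(seq_len(length(pk) - 1), function(q) {
      min(ys[pk[q]:pk[q + 1]])
    }, numeric(1))
    acc <- integer(0)      # accepted peak indices (into ys)
    acc_v <- numeric(0)    # valley between acc[i-1] and acc[i]
    carry_v <- Inf
    for (q in seq_along(pk)) {
      p <- pk[q]
      v <- if (q == 1) Inf else min(carry_v, vall[q - 1])
      carry_v <- Inf
      repeat {
        if (!length(acc)) break
        t <- acc[length(acc)]
        if (min(ys[t], ys[p]) - v >= merge_depth) break
        if (ys[t] >= ys[p]) { carry_v <- v; p <- NA_integer_; break }
        # new peak dominates: drop the stack top, extend the valley left
        acc <- acc[-length(acc)]
        v <- min(v, acc_v[length(acc_v)])
        acc_v <- acc_v[-length(acc_v)]
      }
      if (!is.na(p)) { acc <- c(acc, p); acc_v <- c(acc_v, v) }
    }
    pk <- acc
  }

  tab <- NULL
  for (j in seq_along(pk)) {
    peak_idx <- pk[j]
    # onset: walk left from the peak to the last upward threshold crossing,
    # stopping at the valley shared with the previous event
    left_lim <- if (j == 1) 1L else
      pk[j - 1] + which.min(ys[pk[j - 1]:pk[j]]) - 1L
    i <- peak_idx
    while (i > left_lim && ys[i - 1] > thr) i <- i - 1L
    onset_idx <- i
    base_lo <- max(1L, onset_idx - base_w)
    local_base <- stats::median(y0[base_lo:max(base_lo, onset_idx - 1L)])
    amp <- ys[peak_idx] - local_base
    if (amp <= 0) next
    rise <- rise_time_ms(ys, onset_idx, peak_idx, local_base, amp, fs, base_w)
    tab <- rbind(tab, c(onset_idx, peak_idx, amp, rise))
  }
  if (is.null(tab) || nrow(tab) == 0) return(empty_events())
  onset_t <- (tab[, 1] - 1) / fs
  ev <- data.frame(onset_time = onset_t,
                   peak_time = (tab[, 2] - 1) / fs,
                   amplitude = tab[, 3],
                   rise_time = tab[, 4],
                   preceding_interval = c(NA, diff(onset_t)))
  ev[order(ev$onset_time), , drop = FALSE]
}

empty_events <- function() {
  data.frame(onset_time = numeric(0), peak_time = numeric(0),
             amplitude = numeric(0), rise_time = numeric(0),
             preceding_interval = numeric(0))
}

# 10-90% rise time (ms) by linear interpolation, walking back from the peak.
rise_time_ms <- function(ys, onset_idx, peak_idx, base, amp, fs, back_w) {
  lo <- max(1L, onset_idx - back_w)
  seg <- ys[lo:peak_idx] - base
  n <- length(seg)
  cross <- function(level) {
    target <- level * amp
    below <- which(seg[seq_len(n - 1)] <= target & seg[2:n] > target)
    below <- below[below <= n - 1]
    if (!length(below)) return(NA_real_)
    i <- max(below)  # last upward crossing before the peak
    i + (target - seg[i]) / (seg[i + 1] - seg[i])
  }
  t10 <- cross(0.10); t90 <- cross(0.90)
  if (is.na(t10) || is.na(t90) || t90 <= t10) return(NA_real_)
  (t90 - t10) / fs * 1000
}

#' Select events for per-cell quantification
#'
#' Drops events with rise time at or above the class limit (3 ms for mEPSCs,
#' 5 ms for mIPSCs, strict inequality) and keeps the first `n_target`
#' chronologically. If fewer remain, all are kept and the shortfall is flagged.
#'
#' @param events Event table from [detect_events()], sorted by onset.
#' @param event_class `"mEPSC"` or `"mIPSC"`.
#' @param n_target Number of events to retain (300 by convention).
#' @return The selected subset with attribute `shortfall` (TRUE when fewer
#'   than `n_target` qualified).
#' @export
select_events <- function(events, event_class = c("mEPSC", "mIPSC"), n_target = 300) {
  event_class <- match.arg(event_class)
  limit <- if (event_class == "mEPSC") 3 else 5
  ok <- !is.na(events$rise_time) & events$rise_time < limit
  sel <- events[ok, , drop = FALSE]
  shortfall <- nrow(sel) < n_target
  if (!shortfall) sel <- sel[seq_len(n_target), , drop = FALSE]
  attr(sel, "shortfall") <- shortfall
  sel
}

#' Average non-overlapping events into a mean waveform
#'
#' Only events with no other event onset within `window` ms on either side
#' contribute. Contributing segments are onset-aligned, local-baseline
#' subtracted and averaged; the window should cover at least five decay
#' constants.
#'
#' @param events Selected event table.
#' @param rec The source [sweep_recording].
#' @param window Averaging window, ms.
#' @param polarity Override for the sweep's polarity metadata.
#' @return Numeric waveform (positive magnitude), starting 5 ms before onset,
#'   with attribute `n_averaged`.
#' @export
average_nonoverlapping <- function(events, rec, window = 50, polarity = NULL) {
  stopifnot(inherits(rec, "sweep_recording"))
  if (nrow(events) == 0) stop("no events supplied")
  polarity <- polarity %||% rec$meta$polarity %||% "inward"
  sgn <- if (polarity == "inward") -1 else 1
  fs <- rec$sampling_rate
  y <- sgn * rec$samples
  w_s <- window / 1000
  on <- events$onset_time
  isolated <- vapply(seq_along(on), function(i) {
    !any(abs(on[-i] - on[i]) < w_s)
  }, logical(1))
  if (!any(isolated)) stop("no non-overlapping events within the averaging window")
  pre <- round(0.005 * fs)
  len <- round(w_s * fs)
  segs <- lapply(which(isolated), function(i) {
    i0 <- round(on[i] * fs) + 1L
    if (i0 - pre < 1 || i0 + len > length(y)) return(NULL)
    seg <- y[(i0 - pre):(i0 + len)]
    seg - stats::median(seg[seq_len(pre)])
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs)) stop("no non-overlapping events fully inside the record")
  avg <- Reduce(`+`, segs) / length(segs)
  attr(avg, "n_averaged") <- length(segs)
  attr(avg, "pre_samples") <- pre
  avg
}

#' Summarize a cell's selected miniature events
#'
#' Frequency is `(n - 1) / (last onset - first onset)` of the selected events
#' (selection truncates the record, so the event span, not the sweep duration,
#' is the denominator). Mean amplitude is the arithmetic mean. The averaged
#' waveform uses non-overlapping events only.
#'
#' @param selected Selected event table from [select_events()].
#' @param rec The source [sweep_recording].
#' @param rms_noise RMS noise of the recording (for the summary record).
#' @param event_class `"mEPSC"` or `"mIPSC"`.
#' @param avg_window Averaging window for the mean waveform, ms.
#' @return List of class `cell_mini_summary`: `frequency` (Hz),
#'   `mean_amplitude`, `n_events_used`, `rms_noise`, `averaged_waveform`,
#'   `qc_pass`, `shortfall`.
#' @export
summarize_cell <- function(selected, rec, rms_noise = NA_real_,
                           event_class = c("mEPSC", "mIPSC"), avg_window = 50) {
  event_class <- match.arg(event_class)
  n <- nrow(selected)
  if (n < 2) stop("insufficient events: need at least 2 selected events")
  span <- selected$onset_time[n] - selected$onset_time[1]
  wave <- tryCatch(average_nonoverlapping(selected, rec, window = avg_window),
                   error = function(e) NULL)
  structure(list(
    frequency = (n - 1) / span,
    mean_amplitude = mean(selected$amplitude),
    n_events_used = n,
    rms_noise = rms_noise,
    averaged_waveform = wave,
    qc_pass = if (is.na(rms_noise)) NA else qc_cell(rms_noise, event_class),
    shortfall = isTRUE(attr(selected, "shortfall"))
  ), class = "cell_mini_summary")
}

#' Full per-cell miniature-event analysis
#'
#' Convenience wrapper chaining noise estimation, QC, detection, selection and
#' summary for one recording.
#'
#' @param rec A [sweep_recording].
#' @param event_class `"mEPSC"` or `"mIPSC"`.
#' @param threshold_mult Detection threshold multiplier.
#' @param n_target Events to select.
#' @return A `cell_mini_summary` (with `qc_pass = FALSE` the summary is still
#'   returned but should be excluded downstream).
#' @export
analyze_mini_cell <- function(rec, event_class = c("mEPSC", "mIPSC"),
                              threshold_mult = 3, n_target = 300) {
  event_class <- match.arg(event_class)
  rms <- estimate_rms_noise(rec)
  ev <- detect_events(rec, rms, threshold_mult = threshold_mult)
  sel <- select_events(ev, event_class, n_target = n_target)
  summarize_cell(sel, rec, rms_noise = rms, event_class = event_class)
}
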