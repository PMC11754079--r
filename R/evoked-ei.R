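#' Measure the first peak of an evoked response
#'
#' Implements the first-peak rule: when multiple peaks are present in the
#' post-stimulus window, the magnitude of the first local extremum in the
#' stated polarity is used, restricting the measurement to the monosynaptic
#' component. The first peak counts as clearly resolved only when every later,
#' larger peak is separated from it by a trough at least `trough_frac` (20%)
#' below the first peak; otherwise `resolved = FALSE` and the cell should be
#' discarded downstream.
#'
#' @param trace Numeric current trace.
#' @param stim_onset Stimulus time, s.
#' @param sampling_rate Hz.
#' @param polarity `"inward"` (negative-going) or `"outward"`.
#' @param window Search window after stimulus, ms.
#' @param blank_ms Stimulus-artifact blanking after `stim_onset`, ms.
#' @param trough_frac Minimum fractional trough separating the first peak from
#'   a later larger one.
#' @param smooth_ms Boxcar smoothing before extremum search, ms.
#' @return List: `amplitude` (baseline-to-peak, positive magnitude),
#'   `resolved` flag, `peak_time` (s), `responded` (FALSE when nothing in the
#'   window clears 3x the pre-stimulus noise).
#' @export
measure_first_peak <- function(trace, stim_onset, sampling_rate,
                               polarity = c("inward", "outward"),
                               window = 50, blank_ms = 0.5, trough_frac = 0.2,
                               smooth_ms = 0.5) {
  polarity <- match.arg(polarity)
  if (blank_ms < 0.5) stop("blanking window must start >= 0.5 ms after the stimulus")
  sgn <- if (polarity == "inward") -1 else 1
  fs <- sampling_rate
  on_idx <- round(stim_onset * fs) + 1L
  pre <- trace[seq_len(max(1L, on_idx - 1L))]
  baseline <- stats::median(pre)
  noise_sd <- stats::sd(pre)
  if (!is.finite(noise_sd)) noise_sd <- 0
  y <- sgn * (trace - baseline)
  i0 <- on_idx + ceiling(blank_ms / 1000 * fs)
  i1 <- min(length(y), on_idx + round(window / 1000 * fs))
  if (i0 >= i1) stop("empty search window")
  seg <- boxcar_smooth(y[i0:i1], round(smooth_ms / 1000 * fs))

  floor_amp <- max(3 * noise_sd, 1e-12)
  if (max(seg) <= floor_amp) {
    return(list(amplitude = 0, resolved = TRUE, peak_time = NA_real_,
                responded = FALSE))
  }
  # smoothed-noise scale for distinguishing real troughs from ripple
  sd_sm <- stats::sd(boxcar_smooth(y[seq_len(max(2L, on_idx - 1L))],
                                   round(smooth_ms / 1000 * fs)))
  if (!is.finite(sd_sm)) sd_sm <- 0
  pk <- local_maxima(seg)
  pk <- pk[seg[pk] > floor_amp]
  # a monotone rise ending at the window edge still counts as one peak
  if (!length(pk)) pk <- which.max(seg)
  # merge adjacent maxima whose separating valley is noise-scale ripple only;
  # any deeper shoulder survives merging and faces the 20% resolution test
  while (length(pk) > 1) {
    merged <- FALSE
    for (q in seq_len(length(pk) - 1)) {
      valley <- min(seg[pk[q]:pk[q + 1]])
      lower <- min(seg[pk[q]], seg[pk[q + 1]])
      min_depth <- max(6 * sd_sm, 1e-9 * max(seg))
      if (lower - valley < min_depth) {
        drop <- if (seg[pk[q]] >= seg[pk[q + 1]]) q + 1 else q
        pk <- pk[-drop]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  first <- pk[1]
  amp <- seg[first]
  resolved <- TRUE
  later_larger <- pk[pk > first & seg[pk] > amp]
  for (q in later_larger) {
    trough <- min(seg[first:q])
    if ((amp - trough) / amp < trough_frac) { resolved <- FALSE; break }
  }
  list(amplitude = amp, resolved = resolved,
       peak_time = (i0 + first - 2) / fs, responded = TRUE)
}

#' Compute the per-intensity E/I ratio curve for one cell
#'
#' For each stimulation intensity, measures the excitatory peak on the -55 mV
#' sweep (inward) and the inhibitory peak on the +10 mV sweep (outward) with
#' the first-peak rule, and forms the per-intensity ratio wherever both peaks
#' are resolved and the inhibitory peak is positive. Discarded intensities
#' carry a reason code; the curve length always equals the number of
#' intensities.
#'
#' @param pairs List of evoked pairs as produced by [gen_evoked_series()]
#'   (each with `intensity`, `excitatory`, `inhibitory`, `stim_onset`).
#' @param window,blank_ms,trough_frac Passed to [measure_first_peak()].
#' @return List of class `ei_curve`: `intensities`, `e_peaks`, `i_peaks`,
#'   `ratios` (NA where discarded), `valid`, `discard_flags`.
#' @export
compute_ratio_curve <- function(pairs, window = 50, blank_ms = 0.5,
                                trough_frac = 0.2) {
  if (length(pairs) < 4) stop("at least 4 intensities required")
  n <- length(pairs)
  e_pk <- i_pk <- ratios <- rep(NA_real_, n)
  flags <- rep("", n)
  intensities <- vapply(pairs, function(p) p$intensity, numeric(1))
  for (j in seq_len(n)) {
    p <- pairs[[j]]
    em <- measure_first_peak(p$excitatory$samples, p$stim_onset,
                             p$excitatory$sampling_rate, "inward",
                             window = window, blank_ms = blank_ms,
                             trough_frac = trough_frac)
    im <- measure_first_peak(p$inhibitory$samples, p$stim_onset,
                             p$inhibitory$sampling_rate, "outward",
                             window = window, blank_ms = blank_ms,
                             trough_frac = trough_frac)
    e_pk[j] <- em$amplitude; i_pk[j] <- im$amplitude
    if (!em$responded) flags[j] <- "no_excitatory_response"
    else if (!im$responded) flags[j] <- "no_inhibitory_response"
    else if (!em$resolved) flags[j] <- "unresolved_first_peak_e"
    else if (!im$resolved) flags[j] <- "unresolved_first_peak_i"
    else if (im$amplitude <= 0) flags[j] <- "no_inhibitory_response"
    else ratios[j] <- em$amplitude / im$amplitude
  }
  if (all(is.na(ratios))) stop("all intensities discarded")
  structure(list(intensities = intensities, e_peaks = e_pk, i_peaks = i_pk,
                 ratios = ratios, valid = !is.na(ratios),
                 discard_flags = flags),
            class = "ei_curve")
}

#' Find the stable-intensity range of an E/I ratio curve
#'
#' The stable range is the longest contiguous run of at least `min_run` valid
#' intensities whose ratios have a coefficient of variation at most
#' `cv_limit`; ties go to the run at the highest intensities. This
#' operationalizes the stable-ratio plateau of saturating synaptic
#' recruitment; both knobs are exposed.
#'
#' @param curve An `ei_curve`.
#' @param cv_limit Maximum coefficient of variation (SD/mean).
#' @param min_run Minimum run length.
#' @return Logical stable mask over intensities.
#' @export
find_stable_range <- function(curve, cv_limit = 0.2, min_run = 3) {
  r <- curve$ratios
  n <- length(r)
  if (sum(curve$valid) < min_run) stop("no stable range: too few valid intensities")
  best <- NULL
  for (i in seq_len(n - min_run + 1)) {
    for (j in (i + min_run - 1):n) {
      run <- r[i:j]
      if (any(is.na(run))) next
      cv <- stats::sd(run) / mean(run)
      if (is.na(cv) || cv > cv_limit) next
      len <- j - i + 1
      if (is.null(best) || len > best$len || (len == best$len && j > best$j)) {
        best <- list(i = i, j = j, len = len)
      }
    }
  }
  if (is.null(best)) stop("no stable range")
  mask <- rep(FALSE, n)
  mask[best$i:best$j] <- TRUE
  mask
}

#' Scalar E/I ratio for a cell
#'
#' Mean of the per-intensity ratios within the stable range.
#'
#' @param curve An `ei_curve`.
#' @param zeitgeber_time ZT (h) the animal was killed; one of 0, 6, 12, 18 for
#'   phase pooling.
#' @param circuit Circuit label metadata (`"L2/3-2/3"` or `"L4-2/3"`).
#' @param cv_limit,min_run Stable-range parameters.
#' @return List of class `cell_ei_ratio`: `value`, `n_intensities_used`,
#'   `zeitgeber_time`, `phase` (NA unless ZT is a pooled timepoint),
#'   `circuit`, `stable_mask`.
#' @export
cell_ei_ratio <- function(curve, zeitgeber_time = NA_real_,
                          circuit = "L2/3-2/3", cv_limit = 0.2, min_run = 3) {
  mask <- find_stable_range(curve, cv_limit = cv_limit, min_run = min_run)
  phase <- if (is.na(zeitgeber_time)) NA_character_ else zt_to_phase(zeitgeber_time)
  structure(list(value = mean(curve$ratios[mask]),
                 n_intensities_used = sum(mask),
                 zeitgeber_time = zeitgeber_time,
                 phase = phase, circuit = circuit, stable_mask = mask),
            class = "cell_ei_ratio")
}

#' Pool per-cell E/I ratios into dark/light phase groups
#'
#' ZT0 and ZT18 cells are pooled as dark phase, ZT6 and ZT12 as light phase
#' (the ratio is stable within 4 h of the phase transitions). Any other ZT is
#' an explicit error.
#'
#' @param cells Either a list of `cell_ei_ratio` objects or a `data.frame`
#'   with columns `value` and `zeitgeber_time`.
#' @return `data.frame` with columns `value`, `zeitgeber_time`, `phase`.
#' @export
pool_phase <- function(cells) {
  if (is.data.frame(cells)) {
    df <- cells
  } else {
    df <- data.frame(
      value = vapply(cells, function(c) c$value, numeric(1)),
      zeitgeber_time = vapply(cells, function(c) c$zeitgeber_time, numeric(1)))
  }
  df$phase <- zt_to_phase(df$zeitgeber_time)
  df
}
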