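#' Construct ground truth for periodic-stimulus imaging
#'
#' Per-pixel response amplitude maps for the two eyes, a smooth phase map
#' (retinotopy surrogate), and the true ocular dominance index. Response
#' amplitude is a Gaussian blob (the activated cortical patch) on a small
#' baseline response, with the contralateral eye stronger everywhere, as in
#' normal mouse V1. The true ODI is the mean over the true binocular ROI (the
#' top `roi_fraction` of pixels of the ipsilateral amplitude map) of
#' `(contra - ipsi) / (contra + ipsi)`.
#'
#' @param height,width Map dimensions in pixels.
#' @param contra_peak,ipsi_peak Peak blob amplitudes (intensity units).
#' @param contra_base,ipsi_base Baseline response amplitudes.
#' @param blob_sigma Blob SD in pixels.
#' @param noise_sd Frame noise SD used by the stack generator.
#' @param roi_fraction Fraction of pixels in the true ROI.
#' @return Object of class `imaging_truth` with `contra_amp`, `ipsi_amp`,
#'   `phase_map`, `true_odi`, `noise_sd`, `roi_mask`.
#' @export
gen_imaging_truth <- function(height = 48, width = 48,
                              contra_peak = 3, ipsi_peak = 1.5,
                              contra_base = 0.3, ipsi_base = 0.2,
                              blob_sigma = 10, noise_sd = 0.1,
                              roi_fraction = 0.70) {
  cy <- (height + 1) / 2; cx <- (width + 1) / 2
  d2 <- outer(seq_len(height), seq_len(width),
              function(r, c) (r - cy)^2 + (c - cx)^2)
  blob <- exp(-d2 / (2 * blob_sigma^2))
  contra <- contra_base + (contra_peak - contra_base) * blob
  ipsi <- ipsi_base + (ipsi_peak - ipsi_base) * blob
  phase <- matrix(rep(seq(0, 2 * pi * (1 - 1 / width), length.out = width),
                      each = height), height, width)
  n_roi <- ceiling(roi_fraction * length(ipsi))
  ord <- order(-as.vector(ipsi), seq_along(ipsi))
  roi <- matrix(FALSE, height, width)
  roi[ord[seq_len(n_roi)]] <- TRUE
  od <- (contra - ipsi) / (contra + ipsi)
  structure(list(contra_amp = contra, ipsi_amp = ipsi, phase_map = phase,
                 true_odi = mean(od[roi & (contra + ipsi) > 0]),
                 noise_sd = noise_sd, roi_mask = roi),
            class = "imaging_truth")
}

#' Generate contra/ipsi image stacks from imaging ground truth
#'
#' Each pixel's time series is `amp * cos(2 pi f_stim t + phase)` plus Gaussian
#' noise, covering `n_cycles` full stimulus cycles.
#'
#' @param truth An `imaging_truth` from [gen_imaging_truth()].
#' @param f_stim Stimulus frequency, Hz.
#' @param frame_rate Acquisition rate, Hz.
#' @param n_cycles Number of full stimulus cycles (>= 2).
#' @param seed Integer seed.
#' @param stimulus_extent Stimulus coverage metadata.
#' @return List with `contra` and `ipsi` [image_stack]s.
#' @export
gen_imaging_stack <- function(truth, f_stim = 0.05, frame_rate = 5,
                              n_cycles = 10, seed = 1,
                              stimulus_extent = "binocular_field") {
  stopifnot(inherits(truth, "imaging_truth"), n_cycles >= 2)
  set.seed(as.integer(seed))
  n_frames <- round(n_cycles / f_stim * frame_rate)
  tt <- (seq_len(n_frames) - 1L) / frame_rate
  h <- nrow(truth$contra_amp); w <- ncol(truth$contra_amp)
  make <- function(amp, eye) {
    # pixels x time cosine matrix, then reshape
    ph <- as.vector(truth$phase_map)
    a <- as.vector(amp)
    m <- a * cos(outer(ph, 2 * pi * f_stim * tt, FUN = "+"))
    m <- m + stats::rnorm(length(m), 0, truth$noise_sd)
    image_stack(array(m, dim = c(h, w, n_frames)), frame_rate = frame_rate,
                stimulus_frequency = f_stim, eye = eye,
                stimulus_extent = stimulus_extent)
  }
  list(contra = make(truth$contra_amp, "contra"),
       ipsi = make(truth$ipsi_amp, "ipsi"))
}
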