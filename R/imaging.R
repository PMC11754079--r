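#' Pixelwise Fourier response at the stimulus frequency
#'
#' Extracts each pixel's complex response at the stimulus frequency by
#' single-bin discrete Fourier transform over the trimmed record (an integer
#' number of stimulus cycles), scaled so a pure cosine of amplitude A yields
#' magnitude A.
#'
#' @param stack An [image_stack].
#' @return List of class `response_map`: `magnitude` and `phase` matrices,
#'   `eye`, `stimulus_extent`, `smoothed = FALSE`.
#' @export
fourier_response <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  fr <- stack$frame_rate; f0 <- stack$stimulus_frequency
  frames_per_cycle <- fr / f0
  n_cycles <- floor(d[3] / frames_per_cycle)
  if (n_cycles < 1) stop("stimulus frequency not resolvable on the frame grid")
  n_use <- round(n_cycles * frames_per_cycle)
  if (abs(n_use - n_cycles * frames_per_cycle) > 1e-6) {
    stop("stimulus frequency not resolvable on the frame grid")
  }
  tt <- (seq_len(n_use) - 1L) / fr
  basis <- exp(-2i * pi * f0 * tt)
  m <- matrix(stack$frames[, , seq_len(n_use)], nrow = d[1] * d[2])
  coef <- as.vector(m %*% basis) * (2 / n_use)
  structure(list(magnitude = matrix(Mod(coef), d[1], d[2]),
                 phase = matrix(Arg(coef), d[1], d[2]),
                 eye = stack$eye, stimulus_extent = stack$stimulus_extent,
                 smoothed = FALSE),
            class = "response_map")
}

# 2-D convolution with reflected edges.
conv2_reflect <- function(m, kernel) {
  kh <- (nrow(kernel) - 1L) %/% 2L
  kw <- (ncol(kernel) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  ri <- c(rev(seq_len(kh) + 1L), seq_len(h), h - seq_len(kh))
  ci <- c(rev(seq_len(kw) + 1L), seq_len(w), w - seq_len(kw))
  pad <- m[ri, ci, drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(nrow(kernel))) {
    for (j in seq_len(ncol(kernel))) {
      out <- out + kernel[i, j] * pad[(i - 1L) + seq_len(h), (j - 1L) + seq_len(w)]
    }
  }
  out
}

#' Smooth a response map with a 5x5 Gaussian filter
#'
#' Low-pass Gaussian kernel (5x5, sigma = 1 pixel by default, normalized to
#' unit sum) applied to the magnitude map; edges handled by reflection.
#'
#' @param map A `response_map` of at least 5x5 pixels.
#' @param size Kernel size (odd).
#' @param sigma Gaussian SD in pixels.
#' @return The map with smoothed magnitude and `smoothed = TRUE`.
#' @export
smooth_map <- function(map, size = 5, sigma = 1) {
  stopifnot(inherits(map, "response_map"))
  if (any(dim(map$magnitude) < size)) stop("map smaller than the smoothing kernel")
  half <- (size - 1) / 2
  g <- outer(-half:half, -half:half,
             function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  g <- g / sum(g)
  map$magnitude <- conv2_reflect(map$magnitude, g)
  map$smoothed <- TRUE
  map
}

#' Binocular region of interest from the ipsilateral eye map
#'
#' The ROI is the `fraction` (70% by convention) of pixels with the highest
#' response magnitude in the (smoothed) ipsilateral-eye map. Ties at the
#' cutoff break deterministically in row-major pixel order.
#'
#' @param ipsi_map A `response_map` from the ipsilateral eye.
#' @param fraction Fraction of pixels to keep, in (0, 1].
#' @return Logical matrix ROI mask.
#' @export
binocular_roi <- function(ipsi_map, fraction = 0.70) {
  stopifnot(inherits(ipsi_map, "response_map"))
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  mag <- ipsi_map$magnitude
  n_keep <- ceiling(fraction * length(mag))
  # column-major storage; rank by magnitude then row-major position
  rm_order <- as.vector(t(matrix(seq_along(mag), nrow(mag), ncol(mag))))
  pos <- match(seq_along(mag), rm_order)  # row-major rank of each pixel
  ord <- order(-as.vector(mag), pos)
  mask <- matrix(FALSE, nrow(mag), ncol(mag))
  mask[ord[seq_len(n_keep)]] <- TRUE
  mask
}

#' Ocular dominance index over the binocular ROI
#'
#' Per-pixel ocular dominance `(contra - ipsi) / (contra + ipsi)` over ROI
#' pixels with positive denominator, averaged into the scalar ODI
#' (+1 = fully contralateral).
#'
#' @param contra,ipsi Co-registered `response_map`s (same dimensions).
#' @param roi_mask Logical ROI mask from [binocular_roi()].
#' @return List of class `odi_result`: `odi`, `roi_mask`, `roi_fraction`,
#'   `responsive_pixel_count` (pixels used), `od_map` (per-pixel values, NA
#'   outside the ROI).
#' @export
compute_odi <- function(contra, ipsi, roi_mask) {
  stopifnot(inherits(contra, "response_map"), inherits(ipsi, "response_map"))
  if (!all(dim(contra$magnitude) == dim(ipsi$magnitude))) {
    stop("maps must be co-registered with equal dimensions")
  }
  c_m <- contra$magnitude; i_m <- ipsi$magnitude
  denom <- c_m + i_m
  use <- roi_mask & denom > 0
  if (!any(use)) stop("empty ROI after excluding zero-sum pixels")
  od <- matrix(NA_real_, nrow(c_m), ncol(c_m))
  od[use] <- (c_m[use] - i_m[use]) / denom[use]
  structure(list(odi = mean(od[use]),
                 roi_mask = roi_mask,
                 roi_fraction = sum(roi_mask) / length(roi_mask),
                 responsive_pixel_count = sum(use),
                 od_map = od),
            class = "odi_result")
}

#' Count responsive pixels in a full-field response map
#'
#' A relative measure of V1 size: pixels whose (smoothed) magnitude exceeds
#' the noise floor plus `sd_mult` SDs. The floor and SD are estimated
#' robustly from the map itself (median and scaled MAD), so the minority of
#' activated pixels does not inflate the estimate.
#'
#' @param full_field_map A smoothed `response_map` from full-field
#'   stimulation.
#' @param sd_mult Threshold multiplier.
#' @return Integer count of activated pixels.
#' @export
responsive_area <- function(full_field_map, sd_mult = 3) {
  stopifnot(inherits(full_field_map, "response_map"))
  mag <- as.vector(full_field_map$magnitude)
  floor_mu <- stats::median(mag)
  floor_sd <- stats::mad(mag)
  sum(mag > floor_mu + sd_mult * floor_sd)
}

#' End-to-end ODI from contra/ipsi image stacks
#'
#' Fourier response, 5x5 Gaussian smoothing, top-70% ipsilateral ROI, and ODI
#' in one call.
#'
#' @param contra_stack,ipsi_stack [image_stack]s for the two eyes.
#' @param fraction ROI fraction.
#' @return An `odi_result`.
#' @export
analyze_ocular_dominance <- function(contra_stack, ipsi_stack, fraction = 0.70) {
  cmap <- smooth_map(fourier_response(contra_stack))
  imap <- smooth_map(fourier_response(ipsi_stack))
  roi <- binocular_roi(imap, fraction = fraction)
  compute_odi(cmap, imap, roi)
}
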