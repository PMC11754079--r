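#' Write an image stack as multi-page TIFF plus JSON sidecar
#'
#' Frames are scaled onto \[0, 1\] and stored as 16-bit TIFF pages; the affine
#' scale (`intensity_min`, `intensity_max`), frame rate, stimulus frequency and
#' eye/extent/direction metadata go to `<path>.json`. Round-trips are exact up
#' to 16-bit quantization of the intensity range.
#'
#' @param stack An [image_stack].
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  fr <- stack$frames
  lo <- min(fr); hi <- max(fr)
  if (hi == lo) hi <- lo + 1
  pages <- lapply(seq_len(dim(fr)[3]), function(t) (fr[, , t] - lo) / (hi - lo))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  side <- list(frame_rate = stack$frame_rate,
               stimulus_frequency = stack$stimulus_frequency,
               eye = stack$eye, stimulus_extent = stack$stimulus_extent,
               direction = stack$direction,
               intensity_min = lo, intensity_max = hi)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack from multi-page TIFF plus JSON sidecar
#'
#' @param path TIFF path written by [write_image_stack()]; the metadata sidecar
#'   `<path>.json` must be present.
#' @return An [image_stack].
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop(sprintf("metadata sidecar absent: %s", side_path))
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  fr <- array(0, dim = c(h, w, length(pages)))
  for (t in seq_along(pages)) fr[, , t] <- pages[[t]]
  fr <- fr * (side$intensity_max - side$intensity_min) + side$intensity_min
  image_stack(fr, frame_rate = side$frame_rate,
              stimulus_frequency = side$stimulus_frequency,
              eye = side$eye, stimulus_extent = side$stimulus_extent,
              direction = side$direction)
}
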