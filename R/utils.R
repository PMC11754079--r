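# Shared numerical helpers.

# Centered boxcar smoothing; width forced odd, edges keep original samples.
boxcar_smooth <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2 == 0) width <- width + 1L
  if (width == 1L) return(x)
  y <- stats::filter(x, rep(1 / width, width), sides = 2)
  y <- as.numeric(y)
  na <- is.na(y)
  y[na] <- x[na]
  y
}

# Piecewise-constant per-segment statistic expanded back to sample resolution.
segment_stat <- function(x, n_per_seg, fun) {
  n <- length(x)
  idx <- ceiling(seq_len(n) / n_per_seg)
  vals <- tapply(x, idx, fun)
  as.numeric(vals)[idx]
}

# Local maxima indices of a numeric vector (strictly greater than one
# neighbour, not less than the other; plateaus yield their first index).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  s <- sign(diff(x))
  # carry the last nonzero slope sign through plateaus (vectorized fill)
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  pos <- cumsum(nz)
  vals <- s[nz]
  s <- ifelse(pos > 0, vals[pmax(pos, 1L)], 0)
  which(diff(s) < 0) + 1L
}

# Map zeitgeber times onto the paper's dark/light pooling: dark = {0, 18},
# light = {6, 12}. Any other ZT is an explicit error (no interpolation).
zt_to_phase <- function(zt) {
  vapply(zt, function(z) {
    if (z %in% c(0, 18)) "dark"
    else if (z %in% c(6, 12)) "light"
    else stop(sprintf("zeitgeber time %g is not one of the pooled timepoints {0, 6, 12, 18}", z))
  }, character(1))
}

# Deterministic child seed derived from a master seed and a stream label;
# kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483399) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
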