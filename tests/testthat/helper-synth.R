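# Shared fixtures built in code.

# A sweep with events injected at explicit times (s) — controlled ground
# truth for detector tests.
make_event_sweep <- function(times, amplitude = 20, rise_tau = 0.5,
                             decay_tau = 5, noise_rms = 1.5, duration = 60,
                             fs = 10000, polarity = "inward", seed = 1,
                             dc = 0) {
  set.seed(seed)
  n <- duration * fs
  x <- numeric(n)
  if (length(times)) {
    k <- eiosc::psc_kernel(1, rise_tau, decay_tau, fs)
    for (tm in times) {
      i0 <- floor(tm * fs) + 1L
      i1 <- min(i0 + length(k) - 1L, n)
      x[i0:i1] <- x[i0:i1] + amplitude * k[seq_len(i1 - i0 + 1L)]
    }
  }
  if (polarity == "inward") x <- -x
  x <- x + rnorm(n, 0, noise_rms) + dc
  eiosc::sweep_recording(x, fs, holding_potential = -70,
                         meta = list(polarity = polarity))
}

# Bare E/I ratio curve for stable-range tests.
make_curve <- function(ratios) {
  structure(list(intensities = seq_along(ratios),
                 e_peaks = ratios, i_peaks = rep(1, length(ratios)),
                 ratios = ratios, valid = !is.na(ratios),
                 discard_flags = rep("", length(ratios))),
            class = "ei_curve")
}

# Exhaustive-search oracle for the stable range: longest contiguous all-valid
# run of >= min_run with CV <= cv_limit, ties to the highest intensities.
stable_range_oracle <- function(ratios, cv_limit = 0.2, min_run = 3) {
  n <- length(ratios)
  best <- NULL
  for (i in 1:n) for (j in i:n) {
    if (j - i + 1 < min_run) next
    run <- ratios[i:j]
    if (any(is.na(run))) next
    if (sd(run) / mean(run) > cv_limit) next
    len <- j - i + 1
    if (is.null(best) || len > best$len || (len == best$len && j > best$j)) {
      best <- list(i = i, j = j, len = len)
    }
  }
  if (is.null(best)) return(NULL)
  mask <- rep(FALSE, n)
  mask[best$i:best$j] <- TRUE
  mask
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
mw_enumeration_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U_obs <- min(U1, n1 * n2 - U1)
  subsets <- utils::combn(n1 + n2, n1)
  ranks_all <- seq_len(n1 + n2)
  U_all <- apply(subsets, 2, function(s) sum(ranks_all[s]) - n1 * (n1 + 1) / 2)
  min(1, 2 * mean(U_all <= U_obs))
}
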