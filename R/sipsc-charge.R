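#' Per-segment baselines of a spontaneous-IPSC recording
#'
#' The baseline is estimated and later subtracted for each 500 ms of
#' recording. The default estimator is the 10th percentile of the segment's
#' samples — a robust floor under outward (positive-going) synaptic events;
#' the median is available for cleaner records.
#'
#' A per-segment estimate alone can ride on top of a synaptic event that
#' fills its whole segment; with `guard = TRUE` (default) each segment's
#' baseline is clamped to at most the larger of its two neighbours' estimates.
#' Monotone drift is unaffected (one neighbour is always higher), while a
#' segment fully occupied by an event inherits the surrounding floor.
#'
#' @param rec A [sweep_recording].
#' @param segment Segment length, s.
#' @param estimator `"p10"` (10th percentile) or `"median"`.
#' @param guard Apply the neighbour clamp described above.
#' @return Numeric vector of per-segment baseline values
#'   (`ceiling(duration / segment)` long).
#' @export
segment_baselines <- function(rec, segment = 0.5, estimator = c("p10", "median"),
                              guard = TRUE) {
  stopifnot(inherits(rec, "sweep_recording"))
  estimator <- match.arg(estimator)
  n_per <- round(segment * rec$sampling_rate)
  if (length(rec$samples) < 2 * n_per) stop("recording must span at least 2 segments")
  fun <- if (estimator == "p10") function(x) stats::quantile(x, 0.10, names = FALSE)
         else stats::median
  idx <- ceiling(seq_along(rec$samples) / n_per)
  b <- as.numeric(tapply(rec$samples, idx, fun))
  if (guard && length(b) >= 3) {
    n <- length(b)
    mid <- 2:(n - 1)                        # edge segments are left unclamped
    b[mid] <- pmin(b[mid], pmax(b[mid - 1], b[mid + 1]))
  }
  b
}

#' Unit charge of a spontaneous-IPSC recording
#'
#' Charge is the integral of the baseline-subtracted signal, rectified to
#' positive (outward) deflections — sIPSCs recorded at +10 mV are outward —
#' and normalized by the quantified duration. The normalization makes 3-min
#' and 4-min records directly comparable: unit charge in nA·s per s is
#' numerically the mean baseline-subtracted current in nA.
#'
#' @param rec A [sweep_recording] of 3-4 min (180-240 s); set
#'   `allow_any_duration = TRUE` to lift the range check (tests, pulse
#'   calibrations).
#' @param segment Baseline segment length, s.
#' @param estimator Baseline estimator, see [segment_baselines()].
#' @param allow_any_duration Lift the 180-240 s duration requirement.
#' @return List of class `charge_result`: `unit_charge` (trace units, nA by
#'   convention), `raw_integral` (nA·s), `duration_used` (s), `n_segments`,
#'   `meta` (drug condition, ZT, genotype from the sweep metadata).
#' @export
unit_charge <- function(rec, segment = 0.5, estimator = c("p10", "median"),
                        allow_any_duration = FALSE) {
  stopifnot(inherits(rec, "sweep_recording"))
  estimator <- match.arg(estimator)
  dur <- rec$duration
  if (!allow_any_duration && (dur < 180 || dur > 240)) {
    stop("duration outside [180, 240] s; set allow_any_duration to override")
  }
  n_per <- round(segment * rec$sampling_rate)
  base <- segment_baselines(rec, segment = segment, estimator = estimator)
  idx <- ceiling(seq_along(rec$samples) / n_per)
  resid <- rec$samples - base[idx]
  integral <- sum(pmax(resid, 0)) / rec$sampling_rate
  structure(list(unit_charge = integral / dur,
                 raw_integral = integral,
                 duration_used = dur,
                 n_segments = length(base),
                 meta = rec$meta[c("drug", "zeitgeber_time", "genotype")]),
            class = "charge_result")
}

#' Four-group drug x time-of-day contrast of sIPSC charge
#'
#' Kruskal-Wallis ANOVA on ranks over the vehicle/drug x ZT0/ZT12 groups,
#' followed by Dunn's post-hoc test on the requested contrasts (all pairwise
#' by default), as used for endocannabinoid agonist/antagonist comparisons.
#'
#' @param values Unit-charge values.
#' @param condition Drug condition factor (e.g. vehicle/WIN).
#' @param zt Zeitgeber time factor (e.g. 0/12).
#' @param contrasts Optional list of length-2 character vectors naming group
#'   pairs (`"<condition>.ZT<zt>"` labels); defaults to all pairwise.
#' @return A `stat_test_result` from [kruskal_wallis()] with Dunn's adjusted
#'   p-values attached as `posthoc`.
#' @export
condition_contrast <- function(values, condition, zt, contrasts = NULL) {
  grp <- interaction(condition, paste0("ZT", zt), drop = TRUE, sep = ".")
  counts <- table(grp)
  if (any(counts < 2)) {
    stop(sprintf("empty or singleton group: %s",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  }
  groups <- split(values, grp)
  kw <- kruskal_wallis(groups)
  kw$posthoc <- dunn_posthoc(groups, contrasts = contrasts)
  kw
}
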