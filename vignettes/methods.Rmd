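---
title: "Quantifying the daily E/I oscillation: models, rules, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the daily E/I oscillation: models, rules, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

The cortical excitation/inhibition (E/I) balance in mouse primary visual
cortex is not a fixed quantity: it oscillates across the 24-h light:dark
cycle, high in the dark (active) phase and low in the light (rest) phase.
Asking whether a mutant line has "an elevated E/I ratio" is therefore
ill-posed unless time of day is part of the design — a flattened or
phase-shifted oscillation can masquerade as an increase or decrease depending
on when the measurement is taken.

`eiosc` implements the complete quantification chain such a study needs, as
reusable, tested functions:

1. miniature PSC (mEPSC/mIPSC) event detection and per-cell summaries;
2. evoked E/I ratios from paired-holding-potential voltage clamp;
3. spontaneous-IPSC unit charge for pharmacology comparisons;
4. EEG/EMG sleep architecture and state-conditioned spectra;
5. intrinsic-signal ocular dominance imaging;
6. the statistical battery used across all of these;
7. seeded synthetic-data generators providing every input class with known
   ground truth.

Every analysis constant below is exposed as a function argument; the values
given are the defaults and the reasoning behind them.

# Miniature PSC analysis

## Model

Miniature events are modelled (and detected) as biexponential currents
`A'(e^{-t/tau_d} - e^{-t/tau_r})`, peak-normalized so the configured
amplitude is the baseline-to-peak excursion. Defaults emulate AMPA-receptor
mEPSCs in layer 2/3 pyramidal cells at 10 kHz digitization after 2 kHz
filtering: rise 0.5 ms, decay 5 ms, mean amplitude 15 pA with log-normal
spread (CV 0.3), noise RMS 1.5 pA. The log-normal amplitude law reflects the
positive support and right skew of empirical mini distributions.

## Detection rules

* Noise: RMS of the event-free baseline, by iterative exclusion — remove a
  per-500-ms median baseline, then alternately exclude samples beyond 3x the
  current RMS and recompute until the estimate changes by <1%.
* Quality control: cells enter the analysis only with RMS noise strictly
  below 2 pA (mEPSC) or 4 pA (mIPSC).
* Threshold: 3x RMS noise above the local baseline, applied to the
  polarity-rectified trace after a 0.5-ms boxcar — wide enough to suppress
  single-sample spikes at 10 kHz, narrow enough (about one rise constant) to
  leave sub-millisecond rise times measurable.
* Overlap: candidate peaks are split at local minima between them
  (valley-splitting). Valleys shallower than 6x the smoothed-trace noise SD
  are treated as ripple and merged. The merge criterion deliberately does not
  involve the detection threshold, so raising the threshold multiplier can
  only reduce the detection count.
* Amplitude: smoothed peak minus the median of the 5 ms preceding onset
  (local baseline), making detection invariant to DC offsets.
* Rise time: 10–90% interval by linear interpolation. The 10–90% convention
  is this package's choice; 20–80% is not offered because every inclusion
  rule downstream is calibrated to 10–90%.
* Selection: events with rise time under 3 ms (mEPSC) or 5 ms (mIPSC),
  strictly, and the first 300 chronologically. Chronological selection is
  deterministic and reproducible, which an experimenter's manual choice is
  not; a shortfall below 300 is flagged rather than hidden.
* Frequency: `(n-1)/(last onset - first onset)` over the selected events.
  Selection truncates the record, so the event span — not the sweep duration
  — is the right denominator; with all events retained the two differ by
  one inter-event interval.
* Averaged waveform: only events with no neighbouring onset within ±50 ms
  (about 10 decay constants) contribute, onset-aligned, each local-baseline
  subtracted.

## What validation shows — and what it does not

Across rates 0.5/2/5 Hz at SNR 10 the recovered frequency and mean amplitude
stay within 10% of ground truth (50 seeds per rate, 120 s sweeps at 0.5 Hz
and 60 s otherwise), and the false-positive rate on pure noise is below
0.1 Hz. The generator draws stationary Poisson events in stationary Gaussian
noise; real records add slow drift, seal instability, and non-stationary
event rates, so these figures bound detector error, not biological error.

# Evoked E/I ratio

Excitatory and inhibitory responses are recorded in the same cell at the
reversal potentials of the opposing conductance (-55 mV for excitation,
+10 mV for inhibition, no junction-potential correction), over an increasing
series of stimulation intensities.

* First-peak rule: the first local extremum after the stimulus (0.5-ms
  artifact blanking, 50-ms window) is the monosynaptic response. A first
  peak followed by a larger one without an intervening trough of at least
  20% of the first peak's amplitude is "not clearly resolved" and the
  intensity is discarded; ripple-scale wiggles (under 6x the smoothed
  pre-stimulus noise SD) are not treated as peaks. The 20% figure
  operationalizes a visual judgement and is exposed as `trough_frac`.
* Stable range: the per-intensity ratio of a saturating synaptic recruitment
  curve plateaus once both pathways saturate. The stable range is defined as
  the longest contiguous run of at least `min_run = 3` valid intensities
  whose ratios have coefficient of variation at most `cv_limit = 0.2`, ties
  resolved toward the highest intensities (deepest into saturation). The
  cell's E/I ratio is the mean over that run. Both knobs are exposed; an
  exhaustive search over all contiguous runs is cheap at realistic series
  lengths (4–16 intensities).
* Phase pooling: cells collected at ZT0 and ZT18 form the dark-phase group
  and ZT6/ZT12 the light-phase group; the ratio stabilizes within 4 h of
  the phase transitions, which these timepoints avoid. Any other ZT is an
  error rather than being silently mapped.

The synthetic series drives excitatory and inhibitory peaks along Hill
curves sharing one half-saturation intensity, so a plateau at
`e_max/i_max` exists by construction; optional log-normal jitter below the
half-saturation point creates the unstable low-intensity region the search
must skip. At zero noise the pipeline returns the configured ratio to within
0.2% (the residual is boxcar attenuation of the two kernels' peaks, which
differs slightly between the faster excitatory and slower inhibitory
kinetics); at 5 pA noise the mean recovered ratio stays within 5% over 100
seeds.

# Spontaneous IPSC unit charge

sIPSCs are recorded at +10 mV (outward) and quantified as *unit charge*: the
integral of the baseline-subtracted, positively rectified current divided by
the quantified duration (3–4 min per cell). Dividing by duration makes 3-min
and 4-min records directly comparable; the quantity is numerically the mean
synaptic current in nA. The raw integral is reported alongside.

The baseline is estimated for each 500 ms of recording as the segment's 10th
percentile — a robust floor under outward events (median available via
`estimator`). A segment can still be fully occupied by a long event or
burst; each interior segment's baseline is therefore clamped to at most the
larger of its two neighbours' estimates. Monotone drift always leaves one
neighbour higher, so drift tracking is unaffected, while an event-filled
segment inherits the surrounding floor.

Validation: a 1 nA x 1 s pulse in a 200 s record yields exactly 0.005 nA;
synthetic records (10 Hz events of 0.1 nA mean on a 0.02 nA sinusoidal
drift, 0.5 pA noise) recover the closed-form kernel-integral charge within
10% over 50 seeds. The residual positive bias (~2%) comes from rectified
noise and the sub-baseline cut of event tails; it is common mode across the
drug/time groups the statistic is used to compare.

# Sleep analysis

Hypnograms use 4-s epochs over WAKE/NREM/REM. Architecture reports percent
time per state in 1-h or 12-h bins (summing to 100 per bin), bout counts and
mean durations (a bout is any maximal run, minimum one epoch — no minimum
bout length is imposed), and ordered transition counts. Per-mouse values are
averaged over 3 recording days before statistics.

Spectra are Welch periodograms: 2-s Hann windows (0.5 Hz resolution at
500 Hz sampling), two windows per epoch, never crossing epoch boundaries
(epochs of one state need not be contiguous), averaged within state and
normalized so the 0.5–80 Hz sum is 1. A state with no epochs yields an
absent profile, not zeros. Band definitions are the conventional rodent
bands bounded by the 80 Hz normalization ceiling: delta 0.5–4, theta 5–9,
gamma 30–80 Hz, all config-exposed. Bands are half-open `[lo, hi)` except at
the 80 Hz ceiling, so complementary bands partition the unit total.

The rule-based scorer stands in for manual scoring on synthetic data: WAKE
when epoch EMG RMS exceeds 20 uV; otherwise REM when the theta/delta power
ratio exceeds 1.5; otherwise NREM. On generator defaults it reproduces at
least 90% of ground-truth epochs. It is a validation instrument for the
synthetic pipeline, not a general-purpose scorer: real records are scored
externally and ingested as hypnogram TSVs, and per-animal
`exclude_spectral` metadata handles electrode-placement exclusions.

The generator draws per-epoch states from phase-specific Markov chains
(light phase: mostly asleep; dark: mostly awake; stationary mixes
WAKE/NREM/REM of roughly 46/42/12% light and 79/18/3% dark) and synthesizes
EEG as band-limited Gaussian noise weighted per state (NREM delta-heavy,
REM theta-heavy), EMG as white noise at state-specific RMS. Real EEG has
1/f structure, spindles and artifacts that this deliberately omits: the
synthesis targets exactly the features the scorer and spectral code are
sensitive to, nothing more.

# Intrinsic-signal imaging

Periodic-stimulus stacks are reduced per pixel to the complex response at
the stimulus frequency by single-bin DFT over a whole number of cycles
(trimming any remainder), scaled so a pure cosine of amplitude A yields
magnitude A. Magnitude maps are smoothed with a 5x5 Gaussian (sigma 1 px,
reflected edges). The binocular ROI is the top 70% of pixels of the
*smoothed* ipsilateral map (smoothing precedes selection; ties at the cutoff
break in row-major order for determinism). The ODI is the ROI mean of
`(contra - ipsi)/(contra + ipsi)`, excluding zero-denominator pixels.
"Intensity" for ROI selection means response magnitude, not raw luminance —
the maps being ranked are response maps.

The responsive-area proxy for V1 size counts pixels whose smoothed magnitude
exceeds a noise floor plus 3 SD. Floor and SD are estimated robustly from
the map itself as the median and scaled MAD: the activated region is a
minority of pixels, so these estimates track the background distribution
without being inflated by it, and a blank map yields a count of zero.

Validation: at zero noise the DFT is exact to machine precision; end-to-end,
the generator's true ODI (mean over the true ROI of the configured
amplitude maps, contralateral bias everywhere) is recovered within 0.05 at
SNR 10 over 20 seeds; in practice the error is under 0.001 because the
smooth amplitude maps are nearly invariant under the 5x5 kernel.

# Statistical battery

* Unpaired two-tailed t (pooled variance, df = n1+n2-2); degenerate
  zero-variance equal-mean data give t = 0, p = 1 rather than an error.
* Mann-Whitney: U reported as min(U1, U2); exact two-tailed p from the null
  U distribution when n1+n2 <= 20 without ties, tie-corrected normal
  approximation without continuity correction otherwise — the latter so the
  two-group Kruskal-Wallis identity `H = z^2` holds to numerical precision.
* Kruskal-Wallis with tie correction, chi-square p on k-1 df; Dunn's post
  hoc from pooled tie-corrected ranks.
* Two-way ANOVA with Type-III sums of squares (sum-to-zero contrasts),
  tolerating unbalanced cells — Type III matches the commercial software
  convention this battery mirrors; with a repeated factor, a mixed
  within/between `aov` partition with the repeated factor crossed in
  subject, incomplete subjects dropped with a warning. When one factor is
  constant the design collapses to a one-way fit (so `F = t^2` on two
  groups).
* Holm-Sidak step-down adjustment: sorted ascending,
  `adj_i = max_{j<=i} 1-(1-p_(j))^(m-j+1)`, clipped to 1. The post-hoc
  family is always explicit (genotype-within-phase contrasts by default),
  never inferred from the data.
* Normality gate: Kolmogorov-Smirnov with the Lilliefors correction for
  estimated parameters (a naive-KS mode exists for strict replication);
  any failing group routes the comparison to the nonparametric branch, and
  the decision is recorded in the returned log.
* ROUT outlier flagging at Q = 0.1%: robust center (median) and scale (the
  68.27th percentile of absolute residuals, inverse-ECDF, inflated by
  n/(n-1)), t-tail p-values tested outermost-first against a
  Benjamini-Hochberg-style threshold `Q·i/n`. Below n = 4 nothing is
  tested. Flagging is invariant to affine rescaling.

Calibration (fixed seeds, 1000 null simulations each, n = 12 per group for
t/Mann-Whitney so the normal branch is exercised, 2x2 with n = 10 per cell
for the ANOVA interaction): empirical type-I error of every test falls in
[0.035, 0.065] at alpha = 0.05. Exactness: the Mann-Whitney p equals full
enumeration for every split with n1+n2 <= 8.

# Synthetic study and problem sizes

`run_study()` composes the full design: two genotypes (wild-type
oscillating dark 0.50 / light 0.35; mutant either flat at 0.42 or reversed
0.35/0.50), E/I at ZT 0/6/12/18 with 12 cells per group, minis and charge
at ZT 0/12, sleep architecture from three 24-h days per mouse, and per-animal
ODI — with between-cell log-normal variability (SD 0.15) on every true
value, so group statistics face realistic spread. A reversed mutant produces
a genotype x phase interaction without a main genotype effect, the signature
that distinguishes dysregulation from a level shift.

Problem sizes throughout (sweep durations, seed counts, mice per group,
1-h signal-level sleep records against 24-h hypnogram-level ones) were
chosen as the smallest sizes at which the validation tolerances above are
meaningful sampling-error bounds rather than noise; they are stated in each
test and in `scripts/acceptance.R`.

# Known limitations

* The detectors are threshold-based, matching the commercial tools they
  replace; template-matching or deconvolution detection is out of scope, as
  is kinetics fitting beyond the averaged waveform.
* The stable-range and first-peak criteria quantify judgements that the
  original workflow left to the experimenter; the defaults here are
  declared operationalizations, not recovered constants.
* "Unit charge" is dimensionally charge per time (mean current); the
  conventional label nA/s is kept for continuity but the documentation
  states the units precisely.
* The sleep scorer and EEG synthesis are intentionally minimal; neither
  artifact rejection nor scoring GUIs are provided.
* Conductance decomposition, junction-potential correction and
  series-resistance modelling are excluded by design.
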