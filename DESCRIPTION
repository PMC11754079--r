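Package: eiosc
Title: Quantification of Daily Oscillations in the Cortical Excitation/Inhibition Ratio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for measuring how the cortical excitation/inhibition
    (E/I) balance changes across the 24-h light:dark cycle. Implements miniature
    postsynaptic current (mEPSC/mIPSC) event detection and per-cell summaries under
    RMS-noise and rise-time inclusion rules, evoked E/I ratio quantification from
    paired-holding-potential voltage-clamp recordings with first-peak and
    stable-intensity-range rules, spontaneous IPSC unit-charge quantification with
    per-500-ms baseline subtraction, EEG/EMG sleep architecture and state-conditioned
    normalized power spectra, pixelwise Fourier analysis of periodic-stimulus
    intrinsic-signal imaging with ocular dominance index computation, and the
    accompanying statistical battery (two-tailed t, Mann-Whitney, two-way ANOVA with
    Holm-Sidak post hoc, Kruskal-Wallis with Dunn's post hoc, Lilliefors normality
    gating, ROUT outlier flagging). Seeded synthetic-data generators provide every
    input class with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    rhdf5,
    nortest,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
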