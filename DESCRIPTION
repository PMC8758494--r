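Package: gammaSpike
Title: Gamma Oscillation Power and Spike-Gamma Phase Coupling Analysis
    for Hippocampal Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies kainate-induced gamma oscillations and neuronal
    spike-gamma coupling from local field potential (LFP) and whole-cell
    patch-clamp recordings. Provides segment-averaged power spectra with
    gamma band power and spectral frequency variance; zero-phase
    Butterworth band-pass filtering and Hilbert-transform instantaneous
    phase; amplitude-threshold spike detection and circular spike-phase
    statistics (mean resultant vector length, preferred phase angle,
    Rayleigh uniformity test as an inclusion gate); scaled-template
    detection of postsynaptic currents (EPSC/IPSC amplitude and
    frequency); and a genotype-by-age comparison layer (Shapiro-Wilk
    screen, robust ROUT-style outlier exclusion, two-way ANOVA with
    Holm-Sidak step-down multiple comparisons, control-normalization).
    Calibrated synthetic-data generators with known ground truth (von
    Mises phase-coupled spike trains on a jittered gamma carrier over
    1/f noise, double-exponential synaptic events, full cohort designs)
    allow every stage to be validated by parameter recovery.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
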