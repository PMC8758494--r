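---
title: "Quantifying gamma oscillations and spike-gamma coupling with gammaSpike"
author: "gammaSpike authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gamma oscillations and spike-gamma coupling with gammaSpike}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammaSpike)
```

## The scientific problem

Hippocampal gamma oscillations (30--80 Hz) arise from the rhythmic interplay
of excitatory pyramidal cells (PC) and inhibitory fast-spiking interneurons
(FSN). In slice preparations a persistent gamma rhythm can be induced
pharmacologically (e.g. by bath-applied kainate) and recorded as a local
field potential (LFP), while whole-cell patch clamp of an individual neuron
records its action potentials (APs) and synaptic currents at the same time.
Two questions drive the analysis this package implements:

1. **How strong and how regular is the network rhythm?** Quantified from the
   LFP power spectrum: gamma band power and the spectral dispersion of the
   rhythm (frequency variance).
2. **How precisely does a given neuron lock its spikes to the rhythm?**
   Quantified by circular statistics of the gamma phase at which each AP is
   fired: the mean resultant vector length, the preferred phase angle, and a
   Rayleigh uniformity test used as an inclusion gate.

Around these two cores sit a synaptic-event layer (template detection of
EPSCs/IPSCs, their amplitude and frequency) and a statistical comparison
layer for genotype-by-age cohort designs. Because raw patch-clamp datasets of
this kind are rarely shared, the package also ships a fully parameterized
synthetic-data generator, so that every estimator can be validated by
parameter recovery against known ground truth.

## The coupling model and its estimators

The analysis chain for one cell is:

1. **Band-pass filter** the LFP, 20--40 Hz by default, with a zero-phase
   (forward--backward) Butterworth filter. The effective response is the
   squared Butterworth magnitude and the group delay is zero, so filtering
   cannot bias spike phases.
2. **Instantaneous phase** via the Hilbert transform (frequency-domain
   analytic signal). Convention: the peak of the oscillation cycle is
   phase 0 and the trough is $\pm\pi$.
3. **Spike detection** in the simultaneous current-clamp trace by amplitude
   threshold (default 0 mV), one spike per supra-threshold epoch,
   timestamped at the epoch maximum.
4. **Phase assignment**: each AP contributes a unit vector at the phase of
   the nearest LFP sample. At 5 kHz and a ~30 Hz rhythm the per-sample phase
   step is ~0.04 rad, far below the estimator noise, so no interpolation is
   used.
5. **Circular statistics**: with spike phases $\theta_1,\dots,\theta_n$, the
   mean resultant vector is $\bar R e^{i\bar\theta} = \frac1n\sum_k
   e^{i\theta_k}$. The *vector length* $\bar R \in [0,1]$ measures how
   recurrent firing is at the preferred angle $\bar\theta$ (1 = perfect
   locking, 0 = uniform). The *Rayleigh test* ($Z = n\bar R^2$, with the
   standard finite-$n$ correction series) gates inclusion at $p < 0.05$:
   only cells firing in a phase-related manner enter group comparisons.
   Cells with fewer than `nMin = 10` spikes yield an explicit excluded
   result rather than an unstable estimate.

Group-level preferred angles use the circular mean of per-cell angles;
arithmetic averaging is ill-defined near the $\pm\pi$ wrap point.

```{r chain}
sim <- simulateGammaLfp(gammaLfpParams(duration = 20, seed = 1))
spikes <- simulateCoupledSpikes(sim$phase, couplingParams(meanRate = 15,
                                                          kappa = 4, mu = 0,
                                                          seed = 2))
cellTrace <- simulateApTrace(spikes, samplingRate(sim$lfp), seed = 3)
analyzeCell(sim$lfp, cellTrace)
```

## Spectral metrics

Power spectra are segment-averaged one-sided periodograms: the last 60 s of
recording are cut into 8192-sample segments (Hann taper, 50% overlap by
default), each segment is mean-subtracted before the FFT, and the
density-scaled periodograms are averaged. The defaults are configurable down
to rectangular tapers with disjoint blocks, which mimics plain FFT
averaging. Per-segment mean removal matters: at 8192 points / 5 kHz the bin
width is ~0.61 Hz and DC leakage would otherwise contaminate the 20 Hz edge
of the band.

* **Gamma power** integrates the density over 20--80 Hz (trapezoid, with the
  density interpolated at the exact band edges). Parseval consistency — the
  full-band integral approximates the trace variance — is enforced by tests
  at 5% tolerance.
* **Frequency variance**, the rhythm-regularity measure, is formalized here
  as the power-weighted variance of frequency within the band,
  $\sum_i w_i (f_i - \bar f)^2$ with $w_i = p_i / \sum p_i$. No standard
  formula exists for this quantity in the analysis software the field uses,
  so the choice is isolated in one operation; an alternative reading
  (variance of per-segment peak frequencies) is available as
  `freqVarianceMode = "peak_per_segment"`.
* **Normalization**: band power and frequency variance are divided by the
  mean of the age-matched control group, so controls normalize to mean 1.
  The mean (not median) is used, as the conventional reading of
  normalization to a control group.

The power band (20--80 Hz) deliberately differs from the coupling filter
band (20--40 Hz): the former captures total gamma power, the latter isolates
the dominant rhythm for phase estimation. Both are configurable.

## Synaptic event detection

EPSCs/IPSCs are detected by sliding scaled-template matching. The template
is the pointwise mean of at least 20 representative event snippets
(fewer is an error), baseline-subtracted at onset and scaled to unit peak.
At each lag the template is fitted to the trace by least squares with a free
scale and offset; the detection criterion is the fitted scale divided by the
SD of the fit residual (the standard formalization of template detection in
patch-clamp software; the free offset subsumes a separate per-window
baseline step). Contiguous supra-threshold runs of the criterion yield one
event each, separated by at least one template rise time; detected events
are subtracted and the trace re-scanned once, recovering partially
overlapping events. The default criterion threshold is 3.5 — on synthetic
traces at per-event SNR 5 this operating point gives >95% recall with <0.1
false positives per second on pure noise; the threshold is configurable and
the recall/false-positive tradeoff is monotone in it.

## Group comparisons

The comparison layer mirrors conventional practice for genotype-by-age slice
studies, with every step explicit and auditable:

* **ROUT-style outlier exclusion at Q = 1%.** ROUT is defined for
  regression; for a single descriptive group it degenerates to a robust
  location fit, implemented here as median/MAD-scaled residuals with a
  Benjamini-Hochberg-style false-discovery cut at Q. Applied per group by
  default (configurable to pooled). Flags are returned and logged; data are
  never silently mutated.
* **Shapiro-Wilk normality screen**, reported per group, never used to
  auto-switch tests (the parametric pipeline is applied throughout).
* **Two-way ANOVA** (genotype x age) with Type-II sums of squares, the
  standard choice for the unbalanced cell counts that real recordings
  produce.
* **Per-age control-vs-disease contrasts** on the pooled ANOVA error, with
  **Holm-Sidak step-down adjustment** across the age family
  ($\mathrm{adj}_i = \max_{j \le i} (1 - (1 - p_{(j)})^{m - j + 1})$).

The analysis unit is the cell (or recording); animal ids are carried in the
table so either unit can be selected, but mixed-effects modeling of
animal-level nesting is out of scope and acknowledged as a limitation.

## What the synthetic generators emulate

* **Gamma LFP**: a carrier $A(t)\cos\phi(t)$ with
  $\dot\phi = 2\pi(f_0 + x(t))$, where $x(t)$ is a slow Ornstein-Uhlenbeck
  frequency jitter (correlation time 0.5 s) and $A(t)$ carries a fractional
  OU amplitude jitter (0.2 s), on a $1/f^\beta$ background shaped between
  0.5 Hz and Nyquist. The construction gives an exact ground-truth phase
  track against which the Hilbert estimator is scored. Defaults (60 s at
  5 kHz, 30 Hz carrier, 0.2 mV amplitude, 20% amplitude jitter, 1 Hz
  frequency jitter, 0.05 mV RMS 1/f noise) emulate stable pharmacologically
  induced slice gamma at the acquisition settings typical for such
  recordings.
* **Coupled spikes**: an inhomogeneous Poisson process with intensity
  $\propto \exp(\kappa\cos(\phi(t) - \mu))$ — spike phases are then von
  Mises distributed with concentration $\kappa$, the canonical circular
  analogue of the Gaussian. This is a modeling choice, not an empirical
  claim about FSN/PC phase scatter. Generation is by thinning a homogeneous
  Poisson process, with the intensity renormalized on the realized phase
  track and compensated for refractory dead time (2 ms default) so the
  realized rate matches the requested rate within ~2%. The von Mises mean
  resultant length $I_1(\kappa)/I_0(\kappa)$ provides the analytic recovery
  target.
* **Synaptic traces**: Poisson event times, log-normal amplitudes,
  difference-of-exponentials kernels (0.5 ms rise, 5 ms decay, unit peak)
  on Gaussian noise. Onsets are kept one kernel length from the trace end so
  ground-truth amplitudes are never truncated.
* **Cohorts**: a genotype x age design with per-group multipliers on carrier
  amplitude, coupling concentration, firing rate, event amplitude and event
  rate. Per-cell seeds derive deterministically from the master seed, so a
  design is a pure function of its seed.

What the generators do *not* emulate: biophysical network dynamics (no
conductance-based neurons, no PING mechanism), electrode drift, line noise
(removed in hardware in typical rigs), non-stationary state changes, or
animal-level correlations between cells. Passing recovery tests therefore
demonstrates estimator correctness under the assumed statistical structure,
not robustness to every artifact of real recordings.

## Numerical choices

* **Filter realization.** At 20--40 Hz corners and 5 kHz sampling, a single
  transfer-function Butterworth band-pass of order 4 is numerically unstable
  in double precision (poles cluster near $z = 1$). The filter is therefore
  realized as an order-4 high-pass at the low cut cascaded with an order-4
  low-pass at the high cut, each applied forward-backward. `filterGain()`
  exposes the cascade's theoretical two-pass magnitude for independent
  verification; measured tone attenuation matches it to numerical precision.
  The trace mean is removed before filtering so results are exactly
  invariant to DC offsets.
* **Edge handling.** Spikes within three low-cut cycles (0.15 s at 20 Hz) of
  either trace edge are dropped before phase lookup, avoiding filter
  settling transients; firing rates use the correspondingly shortened
  duration.
* **Inclusion logic.** Exclusions (too few spikes, Rayleigh gate) are
  recorded with reasons, never raised as errors; the pipeline ledger
  accounts for every input cell exactly once.
* **Degenerate inputs.** Constant traces are rejected for phase estimation;
  zero band power is an explicit error for frequency variance; groups with
  fewer than 3 values or zero variance are flagged, not tested, in the
  normality screen; fewer than 5 values is a warning no-op for the outlier
  screen.
* **LFP polarity.** "Peak" means a local maximum of the recorded signal as
  stored. Extracellular field polarity is convention-dependent;
  `invertLfp = TRUE` flips it, which shifts phase angles by $\pi$ and never
  changes vector lengths, so within-convention group comparisons are
  unaffected.

## Problem sizes used in validation

The shipped validation suite exercises the full chain at desk scale: vector
length recovery over $\kappa \in \{0.5, 1, 2, 4, 8\}$ with ~500 spikes per
cell and 50 seeds per $\kappa$ (observed |bias| < 0.05 against
$I_1(\kappa)/I_0(\kappa)$, preferred-angle error < 0.15 rad for
$\kappa \ge 2$); Rayleigh size calibration with 2000 uniform samples of
$n = 50$; and a study-shaped cohort of 2 genotypes x 4 ages x 10 cells with
a 0.6 multiplier on $\kappa$ in the disease group at the three older ages,
which the comparison layer resolves into per-age adjusted significance at
exactly those ages in the large majority of master seeds. These sizes were
chosen to make recovery targets statistically decisive at interactive run
times.

## Known limitations

* ABF (Axon Binary Format) files are not read directly; recordings must be
  exported to CSV (`time_s,value` plus a JSON sidecar, the package's
  archival format).
* Spike-field coherence spectra, phase-amplitude coupling, wavelet phase
  estimation, time-frequency analysis and multitaper estimation are out of
  scope.
* Event kinetics (per-event rise/decay fitting) and deep overlap resolution
  beyond one subtract-and-rescan pass are not implemented.
* Cells are the unit of statistical analysis; animal-level nesting is
  carried in the tables but not modeled.
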