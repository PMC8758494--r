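# gammaSpike

Analysis of hippocampal gamma oscillations and neuronal spike–gamma
coupling from slice electrophysiology, for researchers who record
pharmacologically induced gamma local field potentials (LFP) together with
whole-cell patch-clamp traces and need reproducible, auditable versions of
the standard analysis chain:

* **Gamma power and rhythm regularity** — segment-averaged power spectra
  (8192-point segments of 60 s of LFP by default), band power by integrating
  the spectral density over 20–80 Hz, power-weighted spectral frequency
  variance, and normalization to an age-matched control group.
* **Spike–gamma coupling** — zero-phase Butterworth band-pass (20–40 Hz),
  Hilbert-transform instantaneous phase (peak = 0, trough = ±π),
  amplitude-threshold spike detection, and circular statistics of spike
  phases: the mean resultant vector length
  `R = |Σ exp(iθ_k)| / n` (1 = perfect phase locking, 0 = uniform), the
  preferred phase angle `arg(Σ exp(iθ_k))`, and the Rayleigh uniformity
  test (`Z = n R²`) as an inclusion gate at p < 0.05.
* **Synaptic events** — scaled-template detection of EPSCs/IPSCs (template
  averaged from ≥ 20 representative events; criterion = fitted scale /
  residual SD), with amplitude and frequency summaries.
* **Group comparisons** — ROUT-style outlier exclusion (Q = 1%),
  Shapiro–Wilk normality screen, two-way genotype × age ANOVA (Type-II SS),
  and per-age contrasts with Holm–Šidák step-down adjustment.
* **Synthetic data with ground truth** — a gamma LFP generator with an
  exact phase track, von Mises phase-coupled spike trains
  (intensity ∝ exp(κ·cos(φ − μ)); mean resultant length I₁(κ)/I₀(κ)),
  double-exponential synaptic-current traces, and full genotype × age
  cohort designs, so every estimator is validated by parameter recovery.

## Worked example

Simulate one cell's concomitant recordings — a 20 s gamma LFP and a spike
train coupled to it at concentration κ = 4 — and run the full per-cell
analysis:

```r
library(gammaSpike)

sim       <- simulateGammaLfp(gammaLfpParams(duration = 20, seed = 1))
spikes    <- simulateCoupledSpikes(sim$phase,
                                   couplingParams(meanRate = 15, kappa = 4,
                                                  mu = 0, seed = 2))
cellTrace <- simulateApTrace(spikes, samplingRate(sim$lfp), seed = 3)

analyzeCell(sim$lfp, cellTrace)
#> CouplingResult: n = 263 spikes, vector length 0.875, phase angle -0.027 rad,
#>   Rayleigh p = 2.99e-85, firing rate 13.35 Hz, included

gammaMetrics(computePowerSpectrum(sim$lfp, spectralConfig(analysisDuration = 20)))
#> GammaMetrics [20-80 Hz]: band power 0.02116, peak 29.30 Hz, freq. variance 10.23 Hz^2
```

Reading the output: the cell fired 263 APs at 13.4 Hz; their gamma phases
concentrate near the oscillation peak (angle −0.03 rad ≈ 0) with vector
length 0.875 — close to the analytic von Mises value
I₁(4)/I₀(4) = 0.864 for the generating κ, so the chain (filter → Hilbert
phase → spike detection → circular statistics) recovers the ground truth.
The Rayleigh p ≪ 0.05 marks the cell as phase-locked, so it would enter
group comparisons. The spectrum peaks at 29.3 Hz (carrier 30 Hz) and the
frequency variance of ~10 Hz² reflects the generator's 1 Hz frequency
jitter plus background noise.

Study-shaped runs (simulate or ingest a whole cohort, compare genotypes at
each age) go through `runConfig()` / `runPipeline()`, or the YAML-driven
wrapper in `inst/scripts/run-pipeline.R`:

```sh
Rscript inst/scripts/run-pipeline.R --config run.yaml --out results/
```

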