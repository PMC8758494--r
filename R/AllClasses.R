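# S4 data containers shared by all modules. Parameter/config objects are
# lightweight validated lists (see their constructors); recorded data and
# analysis products are S4 with validity methods.

#' TimeSeries: a uniformly sampled voltage or current trace
#'
#' The universal raw-data container of the package: holds an LFP, a
#' current-clamp or a voltage-clamp trace together with its sampling rate and
#' units. Sample `k` (0-based) corresponds to time `t0 + k / samplingRate`.
#'
#' @slot samples numeric vector of finite sample values (mV or pA).
#' @slot samplingRate sampling rate in Hz (> 0).
#' @slot t0 time of the first sample in seconds.
#' @slot units one of `"mV"`, `"pA"`, `"arbitrary"`.
#' @slot label free-text label (e.g. channel name).
#'
#' @aliases TimeSeries-class
#' @export
setClass("TimeSeries",
  representation(samples = "numeric", samplingRate = "numeric",
                 t0 = "numeric", units = "character", label = "character"))

setValidity("TimeSeries", function(object) {
  if (length(object@samples) < 1L) return("'samples' must have length >= 1")
  if (!all(is.finite(object@samples))) return("all samples must be finite")
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0) return("'samplingRate' must be a single positive number")
  if (length(object@t0) != 1L || !is.finite(object@t0)) return("'t0' must be finite")
  if (!(object@units %in% c("mV", "pA", "arbitrary")))
    return("'units' must be one of mV, pA, arbitrary")
  TRUE
})

#' Construct a TimeSeries
#'
#' @param samples numeric vector of finite sample values.
#' @param samplingRate sampling rate in Hz.
#' @param t0 time of the first sample (seconds); default 0.
#' @param units `"mV"`, `"pA"` or `"arbitrary"`.
#' @param label free-text label.
#' @return a [TimeSeries-class] object.
#' @export
#' @examples
#' ts <- TimeSeries(sin(2 * pi * 30 * seq(0, 1, by = 1 / 5000)), 5000, units = "mV")
#' duration(ts)
TimeSeries <- function(samples, samplingRate, t0 = 0,
                       units = "arbitrary", label = "") {
  new("TimeSeries", samples = as.numeric(samples),
      samplingRate = as.numeric(samplingRate), t0 = as.numeric(t0),
      units = units, label = label)
}

#' SpikeTrain: ordered action-potential times
#'
#' @slot times strictly increasing spike times in seconds, all within
#'   `[0, duration)` of the source trace.
#' @slot duration duration of the source recording in seconds.
#' @aliases SpikeTrain-class
#' @export
setClass("SpikeTrain",
  representation(times = "numeric", duration = "numeric"))

setValidity("SpikeTrain", function(object) {
  if (length(object@duration) != 1L || !is.finite(object@duration) ||
      object@duration <= 0) return("'duration' must be a single positive number")
  t <- object@times
  if (length(t)) {
    if (!all(is.finite(t))) return("spike times must be finite")
    if (any(t < 0) || any(t >= object@duration))
      return("spike times must lie in [0, duration)")
    if (any(diff(t) <= 0)) return("spike times must be strictly increasing")
  }
  TRUE
})

#' Construct a SpikeTrain
#'
#' @param times spike times in seconds, strictly increasing.
#' @param duration source-recording duration in seconds.
#' @return a [SpikeTrain-class] object.
#' @export
SpikeTrain <- function(times, duration) {
  new("SpikeTrain", times = as.numeric(times), duration = as.numeric(duration))
}

#' PhaseSeries: instantaneous phase, one value per sample
#'
#' Phase convention: the peak of the oscillation cycle is 0 and the trough is
#' +/- pi; values lie in `(-pi, pi]`.
#'
#' @slot phases numeric vector of phases in radians, in `(-pi, pi]`.
#' @slot samplingRate sampling rate in Hz.
#' @slot t0 time of the first sample in seconds.
#' @aliases PhaseSeries-class
#' @export
setClass("PhaseSeries",
  representation(phases = "numeric", samplingRate = "numeric", t0 = "numeric"))

setValidity("PhaseSeries", function(object) {
  p <- object@phases
  if (length(p) < 1L) return("'phases' must have length >= 1")
  if (!all(is.finite(p))) return("phases must be finite")
  if (any(p <= -pi - 1e-12) || any(p > pi + 1e-12))
    return("phases must lie in (-pi, pi]")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("'samplingRate' must be positive")
  TRUE
})

#' Construct a PhaseSeries
#'
#' @param phases phases in radians, in `(-pi, pi]` (peak = 0, trough = +/- pi).
#' @param samplingRate sampling rate in Hz.
#' @param t0 time of the first sample (seconds).
#' @return a [PhaseSeries-class] object.
#' @export
PhaseSeries <- function(phases, samplingRate, t0 = 0) {
  new("PhaseSeries", phases = as.numeric(phases),
      samplingRate = as.numeric(samplingRate), t0 = as.numeric(t0))
}

#' PowerSpectrum: segment-averaged one-sided power spectral density
#'
#' @slot frequencies frequencies in Hz, ascending from 0 to Nyquist.
#' @slot psd power density (units^2/Hz) per frequency, non-negative.
#' @slot nSegments number of averaged segments.
#' @slot segPsd matrix of per-segment PSDs (frequencies x segments), kept so
#'   per-segment peak-frequency statistics remain available downstream.
#' @slot config snapshot of the [spectralConfig()] used, plus the sampling rate.
#' @aliases PowerSpectrum-class
#' @export
setClass("PowerSpectrum",
  representation(frequencies = "numeric", psd = "numeric",
                 nSegments = "integer", segPsd = "matrix", config = "list"))

setValidity("PowerSpectrum", function(object) {
  f <- object@frequencies
  if (length(f) != length(object@psd))
    return("'frequencies' and 'psd' must have equal length")
  if (any(diff(f) <= 0)) return("'frequencies' must be strictly increasing")
  if (f[1] != 0) return("'frequencies' must start at 0")
  if (any(object@psd < 0)) return("'psd' must be non-negative")
  if (object@nSegments < 1L) return("'nSegments' must be >= 1")
  TRUE
})

#' Construct a PowerSpectrum
#'
#' Usually produced by [computePowerSpectrum()]; the constructor is exported
#' so synthetic spectra (e.g. analytically flat ones) can be built directly.
#'
#' @param frequencies frequencies in Hz, ascending from 0.
#' @param psd one-sided power density per frequency.
#' @param nSegments number of averaged segments.
#' @param segPsd optional matrix of per-segment PSDs.
#' @param config optional list describing how the spectrum was computed.
#' @return a [PowerSpectrum-class] object.
#' @export
PowerSpectrum <- function(frequencies, psd, nSegments = 1L,
                          segPsd = NULL, config = list()) {
  if (is.null(segPsd)) segPsd <- matrix(psd, ncol = 1L)
  new("PowerSpectrum", frequencies = as.numeric(frequencies),
      psd = as.numeric(psd), nSegments = as.integer(nSegments),
      segPsd = segPsd, config = config)
}

#' GammaMetrics: band power, peak frequency and frequency variance
#'
#' @slot bandPower integrated power density over the gamma band (units^2).
#' @slot peakFrequency frequency of maximal density within the band (Hz).
#' @slot frequencyVariance power-weighted spectral variance within the band (Hz^2).
#' @slot normalizedPower band power divided by the control-group mean
#'   (unitless); `NA` until normalization is applied.
#' @slot band the `(low, high)` band in Hz.
#' @aliases GammaMetrics-class
#' @export
setClass("GammaMetrics",
  representation(bandPower = "numeric", peakFrequency = "numeric",
                 frequencyVariance = "numeric", normalizedPower = "numeric",
                 band = "numeric"))

setValidity("GammaMetrics", function(object) {
  if (object@bandPower < 0) return("'bandPower' must be >= 0")
  if (!is.na(object@frequencyVariance) && object@frequencyVariance < 0)
    return("'frequencyVariance' must be >= 0")
  if (length(object@band) == 2L && is.finite(object@peakFrequency) &&
      (object@peakFrequency < object@band[1] || object@peakFrequency > object@band[2]))
    return("'peakFrequency' must lie within 'band'")
  TRUE
})

#' CouplingResult: per-cell spike-gamma coupling summary
#'
#' Vector length is the mean resultant length `|sum(exp(i * theta))| / n` of
#' the spike phase angles; the phase angle is the argument of the resultant;
#' the Rayleigh test provides the inclusion gate (`included` iff
#' `rayleighP < alpha`). Cells with fewer than the minimum spike count carry
#' an `excludedReason` instead of coupling statistics.
#'
#' @slot nSpikes number of spikes entering the statistics.
#' @slot vectorLength mean resultant length in `[0, 1]` (`NA` if excluded).
#' @slot phaseAngle preferred phase angle in `(-pi, pi]` (`NA` if excluded).
#' @slot rayleighP Rayleigh circular-uniformity p value (`NA` if excluded).
#' @slot firingRate spikes per second over the analysis duration.
#' @slot included logical inclusion flag (`rayleighP < alpha`).
#' @slot alpha significance level of the inclusion gate.
#' @slot excludedReason empty string, or why no statistics were computed.
#' @slot provenance list of configuration used (filter, detection, counts).
#' @aliases CouplingResult-class
#' @export
setClass("CouplingResult",
  representation(nSpikes = "integer", vectorLength = "numeric",
                 phaseAngle = "numeric", rayleighP = "numeric",
                 firingRate = "numeric", included = "logical",
                 alpha = "numeric", excludedReason = "character",
                 provenance = "list"))

setValidity("CouplingResult", function(object) {
  vl <- object@vectorLength
  if (!is.na(vl) && (vl < 0 || vl > 1 + 1e-12))
    return("'vectorLength' must lie in [0, 1]")
  p <- object@rayleighP
  if (!is.na(p) && (p <= 0 || p > 1)) return("'rayleighP' must lie in (0, 1]")
  if (!is.na(p) && object@included != (p < object@alpha))
    return("'included' must equal (rayleighP < alpha)")
  TRUE
})

#' EventTemplate: unit-peak average waveform of postsynaptic currents
#'
#' @slot waveform numeric vector with maximal absolute value 1.
#' @slot samplingRate sampling rate in Hz.
#' @slot nSourceEvents number of events averaged (>= 20).
#' @slot polarity `"inward"` (negative-going) or `"outward"`.
#' @aliases EventTemplate-class
#' @export
setClass("EventTemplate",
  representation(waveform = "numeric", samplingRate = "numeric",
                 nSourceEvents = "integer", polarity = "character"))

setValidity("EventTemplate", function(object) {
  if (length(object@waveform) < 2L) return("'waveform' must have length >= 2")
  if (abs(max(abs(object@waveform)) - 1) > 1e-9)
    return("'waveform' must have unit peak magnitude")
  if (object@nSourceEvents < 20L)
    return("a template must average at least 20 source events")
  if (!(object@polarity %in% c("inward", "outward")))
    return("'polarity' must be 'inward' or 'outward'")
  TRUE
})

#' DetectedEvents: onsets, amplitudes and detection statistics
#'
#' @slot times event onset times in seconds, strictly increasing.
#' @slot amplitudes fitted event amplitudes in pA, sign-consistent with the
#'   template polarity.
#' @slot criterion detection statistic per event (fitted scale / residual SD).
#' @slot threshold the criterion threshold used.
#' @slot polarity template polarity the detection used.
#' @aliases DetectedEvents-class
#' @export
setClass("DetectedEvents",
  representation(times = "numeric", amplitudes = "numeric",
                 criterion = "numeric", threshold = "numeric",
                 polarity = "character"))

setValidity("DetectedEvents", function(object) {
  n <- length(object@times)
  if (length(object@amplitudes) != n || length(object@criterion) != n)
    return("'times', 'amplitudes' and 'criterion' must have equal length")
  if (n > 1L && any(diff(object@times) <= 0))
    return("'times' must be strictly increasing")
  if (n > 0L) {
    sgn <- if (object@polarity == "inward") -1 else 1
    if (any(object@amplitudes * sgn < 0))
      return("'amplitudes' must be sign-consistent with polarity")
  }
  TRUE
})

#' ComparisonResult: two-way ANOVA plus per-age Holm-Sidak contrasts
#'
#' @slot anova data.frame with one row per term (genotype, age, interaction,
#'   residuals): sum of squares, df, F, p.
#' @slot pairwise data.frame of per-age control-vs-disease contrasts with raw
#'   and Holm-Sidak adjusted p values.
#' @slot outliersRemoved character ids of rows excluded by the ROUT-style screen.
#' @slot normality data.frame of per-group Shapiro-Wilk p values.
#' @slot alpha significance level used for flagging.
#' @slot notes character notes on the procedure (e.g. outlier-screen variant).
#' @aliases ComparisonResult-class
#' @export
setClass("ComparisonResult",
  representation(anova = "data.frame", pairwise = "data.frame",
                 outliersRemoved = "character", normality = "data.frame",
                 alpha = "numeric", notes = "character"))

setValidity("ComparisonResult", function(object) {
  pw <- object@pairwise
  if (nrow(pw) && any(pw$adjP + 1e-12 < pw$rawP, na.rm = TRUE))
    return("adjusted p values must be >= raw p values")
  TRUE
})

#' RunReport: full output of a study-shaped pipeline run
#'
#' @slot perCell data.frame with one row per input cell and all per-cell
#'   metrics (gamma metrics, coupling, event statistics, inclusion flags).
#' @slot tables named list of per-metric cohort tables (see [cohortTable()]).
#' @slot comparisons named list of [ComparisonResult-class] objects (or
#'   failure notes) per metric.
#' @slot ledger data.frame of excluded cells / quarantined failures with
#'   stage and reason.
#' @slot provenance list: configuration, master seed, package version.
#' @aliases RunReport-class
#' @export
setClass("RunReport",
  representation(perCell = "data.frame", tables = "list",
                 comparisons = "list", ledger = "data.frame",
                 provenance = "list"))
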