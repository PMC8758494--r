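# setMethod implementations of the accessor generics, plus show() methods.

#' @rdname accessors
#' @export
setMethod("samples", "TimeSeries", function(object) object@samples)
#' @rdname accessors
#' @export
setMethod("samplingRate", "TimeSeries", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "PhaseSeries", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EventTemplate", function(object) object@samplingRate)
#' @rdname accessors
#' @export
setMethod("startTime", "TimeSeries", function(object) object@t0)
#' @rdname accessors
#' @export
setMethod("startTime", "PhaseSeries", function(object) object@t0)
#' @rdname accessors
#' @export
setMethod("traceUnits", "TimeSeries", function(object) object@units)
#' @rdname accessors
#' @export
setMethod("traceLabel", "TimeSeries", function(object) object@label)

#' @rdname accessors
#' @export
setMethod("duration", "TimeSeries", function(object)
  length(object@samples) / object@samplingRate)
#' @rdname accessors
#' @export
setMethod("duration", "SpikeTrain", function(object) object@duration)
#' @rdname accessors
#' @export
setMethod("duration", "PhaseSeries", function(object)
  length(object@phases) / object@samplingRate)

#' @rdname accessors
#' @export
setMethod("spikeTimes", "SpikeTrain", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("nSpikes", "SpikeTrain", function(object) length(object@times))
#' @rdname accessors
#' @export
setMethod("phases", "PhaseSeries", function(object) object@phases)

#' @rdname accessors
#' @export
setMethod("frequencies", "PowerSpectrum", function(object) object@frequencies)
#' @rdname accessors
#' @export
setMethod("psd", "PowerSpectrum", function(object) object@psd)
#' @rdname accessors
#' @export
setMethod("nSegments", "PowerSpectrum", function(object) object@nSegments)

#' @rdname accessors
#' @export
setMethod("bandPower", "GammaMetrics", function(object) object@bandPower)
#' @rdname accessors
#' @export
setMethod("peakFrequency", "GammaMetrics", function(object) object@peakFrequency)

#' @rdname accessors
#' @export
setMethod("nSpikes", "CouplingResult", function(object) object@nSpikes)
#' @rdname accessors
#' @export
setMethod("vectorLength", "CouplingResult", function(object) object@vectorLength)
#' @rdname accessors
#' @export
setMethod("phaseAngle", "CouplingResult", function(object) object@phaseAngle)
#' @rdname accessors
#' @export
setMethod("rayleighP", "CouplingResult", function(object) object@rayleighP)
#' @rdname accessors
#' @export
setMethod("firingRate", "CouplingResult", function(object) object@firingRate)
#' @rdname accessors
#' @export
setMethod("isIncluded", "CouplingResult", function(object) object@included)
#' @rdname accessors
#' @export
setMethod("excludedReason", "CouplingResult", function(object) object@excludedReason)

#' @rdname accessors
#' @export
setMethod("templateWaveform", "EventTemplate", function(object) object@waveform)
#' @rdname accessors
#' @export
setMethod("polarity", "EventTemplate", function(object) object@polarity)
#' @rdname accessors
#' @export
setMethod("polarity", "DetectedEvents", function(object) object@polarity)
#' @rdname accessors
#' @export
setMethod("eventTimes", "DetectedEvents", function(object) object@times)
#' @rdname accessors
#' @export
setMethod("eventAmplitudes", "DetectedEvents", function(object) object@amplitudes)

#' @rdname accessors
#' @export
setMethod("anovaTable", "ComparisonResult", function(object) object@anova)
#' @rdname accessors
#' @export
setMethod("pairwiseTable", "ComparisonResult", function(object) object@pairwise)

#' @rdname accessors
#' @export
setMethod("perCellTable", "RunReport", function(object) object@perCell)
#' @rdname accessors
#' @export
setMethod("inclusionLedger", "RunReport", function(object) object@ledger)

# show() methods ---------------------------------------------------------

setMethod("show", "TimeSeries", function(object) {
  cat(sprintf("TimeSeries: %d samples @ %g Hz (%.3f s), units %s%s\n",
              length(object@samples), object@samplingRate,
              duration(object), object@units,
              if (nzchar(object@label)) paste0(", '", object@label, "'") else ""))
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain: %d spikes over %.3f s (%.2f Hz)\n",
              length(object@times), object@duration,
              length(object@times) / object@duration))
})

setMethod("show", "PhaseSeries", function(object) {
  cat(sprintf("PhaseSeries: %d samples @ %g Hz, convention peak = 0, trough = +/-pi\n",
              length(object@phases), object@samplingRate))
})

setMethod("show", "PowerSpectrum", function(object) {
  cat(sprintf("PowerSpectrum: %d bins, 0-%.1f Hz (df = %.4g Hz), %d segment%s\n",
              length(object@frequencies), max(object@frequencies),
              object@frequencies[2] - object@frequencies[1],
              object@nSegments, if (object@nSegments == 1L) "" else "s"))
})

setMethod("show", "GammaMetrics", function(object) {
  cat(sprintf("GammaMetrics [%g-%g Hz]: band power %.4g, peak %.2f Hz, freq. variance %.2f Hz^2%s\n",
              object@band[1], object@band[2], object@bandPower,
              object@peakFrequency, object@frequencyVariance,
              if (is.na(object@normalizedPower)) ""
              else sprintf(", normalized power %.3f", object@normalizedPower)))
})

setMethod("show", "CouplingResult", function(object) {
  if (nzchar(object@excludedReason)) {
    cat(sprintf("CouplingResult: excluded (%s); n = %d spikes, firing rate %.2f Hz\n",
                object@excludedReason, object@nSpikes, object@firingRate))
  } else {
    cat(sprintf(paste0("CouplingResult: n = %d spikes, vector length %.3f, ",
                       "phase angle %.3f rad, Rayleigh p = %.3g, firing rate %.2f Hz, %s\n"),
                object@nSpikes, object@vectorLength, object@phaseAngle,
                object@rayleighP, object@firingRate,
                if (object@included) "included" else "not included"))
  }
})

setMethod("show", "EventTemplate", function(object) {
  cat(sprintf("EventTemplate: %d samples @ %g Hz, %s, averaged from %d events\n",
              length(object@waveform), object@samplingRate, object@polarity,
              object@nSourceEvents))
})

setMethod("show", "DetectedEvents", function(object) {
  cat(sprintf("DetectedEvents: %d %s events (criterion threshold %.2f)\n",
              length(object@times), object@polarity, object@threshold))
  if (length(object@times))
    cat(sprintf("  mean |amplitude| %.2f pA\n", mean(abs(object@amplitudes))))
})

setMethod("show", "ComparisonResult", function(object) {
  cat("ComparisonResult\n  ANOVA:\n")
  print(object@anova, row.names = FALSE)
  cat("  Per-age contrasts (Holm-Sidak adjusted):\n")
  print(object@pairwise, row.names = FALSE)
  if (length(object@outliersRemoved))
    cat(sprintf("  outliers removed: %s\n",
                paste(object@outliersRemoved, collapse = ", ")))
})

setMethod("show", "RunReport", function(object) {
  cat(sprintf("RunReport: %d cells, %d metric tables, %d comparisons, %d ledger entries\n",
              nrow(object@perCell), length(object@tables),
              length(object@comparisons), nrow(object@ledger)))
})
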