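# Accessor generics. Slots are never accessed with @ by user code.

#' @name accessors
#' @title Accessors for gammaSpike data classes
#' @description Read-only accessors for the S4 containers.
#' @param object an object of the documented classes.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("startTime", function(object) standardGeneric("startTime"))

#' @rdname accessors
#' @export
setGeneric("traceUnits", function(object) standardGeneric("traceUnits"))

#' @rdname accessors
#' @export
setGeneric("traceLabel", function(object) standardGeneric("traceLabel"))

#' @rdname accessors
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))

#' @rdname accessors
#' @export
setGeneric("phases", function(object) standardGeneric("phases"))

#' @rdname accessors
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))

#' @rdname accessors
#' @export
setGeneric("psd", function(object) standardGeneric("psd"))

#' @rdname accessors
#' @export
setGeneric("nSegments", function(object) standardGeneric("nSegments"))

#' @rdname accessors
#' @export
setGeneric("bandPower", function(object) standardGeneric("bandPower"))

#' @rdname accessors
#' @export
setGeneric("peakFrequency", function(object) standardGeneric("peakFrequency"))

#' @rdname accessors
#' @export
setGeneric("nSpikes", function(object) standardGeneric("nSpikes"))

#' @rdname accessors
#' @export
setGeneric("vectorLength", function(object) standardGeneric("vectorLength"))

#' @rdname accessors
#' @export
setGeneric("phaseAngle", function(object) standardGeneric("phaseAngle"))

#' @rdname accessors
#' @export
setGeneric("rayleighP", function(object) standardGeneric("rayleighP"))

#' @rdname accessors
#' @export
setGeneric("firingRate", function(object) standardGeneric("firingRate"))

#' @rdname accessors
#' @export
setGeneric("isIncluded", function(object) standardGeneric("isIncluded"))

#' @rdname accessors
#' @export
setGeneric("excludedReason", function(object) standardGeneric("excludedReason"))

#' @rdname accessors
#' @export
setGeneric("templateWaveform", function(object) standardGeneric("templateWaveform"))

#' @rdname accessors
#' @export
setGeneric("polarity", function(object) standardGeneric("polarity"))

#' @rdname accessors
#' @export
setGeneric("eventTimes", function(object) standardGeneric("eventTimes"))

#' @rdname accessors
#' @export
setGeneric("eventAmplitudes", function(object) standardGeneric("eventAmplitudes"))

#' @rdname accessors
#' @export
setGeneric("anovaTable", function(object) standardGeneric("anovaTable"))

#' @rdname accessors
#' @export
setGeneric("pairwiseTable", function(object) standardGeneric("pairwiseTable"))

#' @rdname accessors
#' @export
setGeneric("perCellTable", function(object) standardGeneric("perCellTable"))

#' @rdname accessors
#' @export
setGeneric("inclusionLedger", function(object) standardGeneric("inclusionLedger"))
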