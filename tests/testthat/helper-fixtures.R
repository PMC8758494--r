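# Shared fixtures, all built in code.

makeTone <- function(freq, duration = 10, fs = 5000, amp = 1, phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  TimeSeries(amp * cos(2 * pi * freq * t + phase), fs, units = "mV",
             label = sprintf("%g Hz tone", freq))
}

# indices of strict local maxima
localMaxima <- function(x) which(diff(sign(diff(x))) == -2) + 1L

# mean resultant length of a von Mises distribution
vonMisesVL <- function(kappa) besselI(kappa, 1) / besselI(kappa, 0)

# fraction of true onsets with a detection within tol seconds
eventRecall <- function(trueOnsets, detTimes, tol = 0.002) {
  if (!length(trueOnsets)) return(NA_real_)
  mean(vapply(trueOnsets, function(o) any(abs(detTimes - o) < tol), logical(1)))
}

# detected amplitude matched to each true onset (NA when unmatched)
matchedAmplitudes <- function(trueOnsets, detTimes, detAmps, tol = 0.002) {
  vapply(trueOnsets, function(o) {
    i <- which.min(abs(detTimes - o))
    if (length(i) && abs(detTimes[i] - o) < tol) detAmps[i] else NA_real_
  }, numeric(1))
}

# root-mean-square of a trace segment, dropping edge transients
rmsInterior <- function(ts, dropSeconds = 1) {
  x <- samples(ts)
  k <- round(dropSeconds * samplingRate(ts))
  x <- x[(k + 1):(length(x) - k)]
  sqrt(mean(x^2))
}
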