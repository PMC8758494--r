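# Segment-averaged power spectra of LFP recordings and derived gamma
# metrics: band power by integration of the spectral density, peak frequency,
# and the power-weighted spectral frequency variance.

#' Configuration of the power-spectrum estimator
#'
#' Defaults follow the analysis conventions for slice gamma recordings:
#' 8192-point segments of the last 60 s of recording, Hann taper with 50%
#' overlap (set `window = "rectangular"`, `overlapFraction = 0` to mimic
#' plain averaged FFTs of disjoint blocks), gamma band 20-80 Hz.
#'
#' @param segmentLength FFT segment length in samples (>= 2).
#' @param window `"hann"` or `"rectangular"` taper.
#' @param overlapFraction fraction of segment overlap in `[0, 1)`.
#' @param analysisDuration analysis window in seconds: the last
#'   `analysisDuration` seconds of the trace are used (whole trace if shorter).
#' @param bandLow,bandHigh gamma band limits in Hz.
#' @param freqVarianceMode `"weighted"` (power-weighted spectral variance,
#'   default) or `"peak_per_segment"` (variance of per-segment peak
#'   frequencies) — see [frequencyVariance()].
#' @return a validated list of class `SpectralConfig`.
#' @export
spectralConfig <- function(segmentLength = 8192,
                           window = c("hann", "rectangular"),
                           overlapFraction = 0.5, analysisDuration = 60,
                           bandLow = 20, bandHigh = 80,
                           freqVarianceMode = c("weighted", "peak_per_segment")) {
  window <- match.arg(window)
  freqVarianceMode <- match.arg(freqVarianceMode)
  assertScalar(segmentLength, "segmentLength", lower = 2)
  assertScalar(overlapFraction, "overlapFraction", lower = 0, upper = 1,
               strictUpper = TRUE)
  assertScalar(analysisDuration, "analysisDuration", lower = 0, strictLower = TRUE)
  assertScalar(bandLow, "bandLow", lower = 0, strictLower = TRUE)
  assertScalar(bandHigh, "bandHigh", lower = bandLow, strictLower = TRUE)
  structure(list(segmentLength = as.integer(segmentLength), window = window,
                 overlapFraction = overlapFraction,
                 analysisDuration = analysisDuration,
                 bandLow = bandLow, bandHigh = bandHigh,
                 freqVarianceMode = freqVarianceMode),
            class = "SpectralConfig")
}

#' Segment-averaged one-sided power spectral density
#'
#' Splits the analysis window (the last `analysisDuration` seconds of the
#' trace) into tapered, optionally overlapping segments, removes each
#' segment's mean (DC leakage otherwise contaminates the low end of the gamma
#' band at the default resolution), and averages the per-segment one-sided
#' periodograms with density scaling: the integral of the PSD over
#' `[0, Nyquist]` approximates the sample variance of the detrended trace.
#'
#' @param ts a [TimeSeries-class].
#' @param cfg a [spectralConfig()].
#' @return a [PowerSpectrum-class].
#' @export
#' @examples
#' sim <- simulateGammaLfp(gammaLfpParams(duration = 10, seed = 1))
#' ps <- computePowerSpectrum(sim$lfp, spectralConfig(analysisDuration = 10))
#' gammaMetrics(ps)
computePowerSpectrum <- function(ts, cfg = spectralConfig()) {
  if (!is(ts, "TimeSeries")) stop("'ts' must be a TimeSeries", call. = FALSE)
  if (!inherits(cfg, "SpectralConfig"))
    stop("'cfg' must be created with spectralConfig()", call. = FALSE)
  x <- samples(ts)
  fs <- samplingRate(ts)
  L <- cfg$segmentLength
  if (length(x) < L)
    stop(sprintf("trace too short for spectral analysis: %d samples, at least %d (one segment) required",
                 length(x), L), call. = FALSE)
  nUse <- min(length(x), round(cfg$analysisDuration * fs))
  nUse <- max(nUse, L)
  x <- x[(length(x) - nUse + 1L):length(x)]
  step <- max(1L, round(L * (1 - cfg$overlapFraction)))
  starts <- seq(1L, nUse - L + 1L, by = step)
  w <- if (cfg$window == "hann") {
    0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  } else rep(1, L)
  U <- sum(w^2)
  nf <- L %/% 2L + 1L
  onesided <- rep(2, nf)
  onesided[1] <- 1
  if (L %% 2L == 0L) onesided[nf] <- 1
  segPsd <- matrix(0, nrow = nf, ncol = length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + L - 1L)]
    seg <- seg - mean(seg)
    X <- fft(w * seg)
    segPsd[, j] <- onesided * Mod(X[seq_len(nf)])^2 / (fs * U)
  }
  freqs <- (seq_len(nf) - 1) * fs / L
  PowerSpectrum(frequencies = freqs, psd = rowMeans(segPsd),
                nSegments = length(starts), segPsd = segPsd,
                config = c(unclass(cfg), list(samplingRate = fs)))
}

bandIndices <- function(ps, lo, hi) {
  f <- frequencies(ps)
  if (lo >= hi) stop("'lo' must be less than 'hi'", call. = FALSE)
  if (lo < min(f) || hi > max(f))
    stop(sprintf("band [%g, %g] Hz outside spectrum range [%g, %g] Hz",
                 lo, hi, min(f), max(f)), call. = FALSE)
  which(f >= lo & f <= hi)
}

#' Integrate the power spectral density over a frequency band
#'
#' Trapezoidal integral of the PSD over `[lo, hi]`, with linear interpolation
#' of the density at the exact band edges.
#'
#' @param ps a [PowerSpectrum-class].
#' @param lo,hi band limits in Hz (within the spectrum range).
#' @return band power (units^2), non-negative.
#' @export
integrateBandPower <- function(ps, lo = 20, hi = 80) {
  if (!is(ps, "PowerSpectrum")) stop("'ps' must be a PowerSpectrum", call. = FALSE)
  bandIndices(ps, lo, hi)      # validates the band
  f <- frequencies(ps)
  p <- psd(ps)
  inner <- f > lo & f < hi
  fg <- c(lo, f[inner], hi)
  pg <- c(approx(f, p, xout = lo)$y, p[inner], approx(f, p, xout = hi)$y)
  sum(diff(fg) * (head(pg, -1) + tail(pg, -1)) / 2)
}

#' Spectral frequency variance within a band
#'
#' Default (`mode = "weighted"`): the power-weighted variance of frequency
#' over the band, `sum(w_i * (f_i - fbar)^2)` with `w_i = psd_i / sum(psd)`
#' restricted to the band — a rhythm-regularity measure (larger = more
#' irregular). The alternative `mode = "peak_per_segment"` returns the
#' variance of the per-segment peak frequencies within the band.
#'
#' @param ps a [PowerSpectrum-class].
#' @param lo,hi band limits in Hz.
#' @param mode `"weighted"` or `"peak_per_segment"`; defaults to the mode
#'   recorded in the spectrum's config.
#' @return frequency variance in Hz^2.
#' @export
frequencyVariance <- function(ps, lo = 20, hi = 80, mode = NULL) {
  if (!is(ps, "PowerSpectrum")) stop("'ps' must be a PowerSpectrum", call. = FALSE)
  if (is.null(mode))
    mode <- if (!is.null(ps@config$freqVarianceMode))
      ps@config$freqVarianceMode else "weighted"
  mode <- match.arg(mode, c("weighted", "peak_per_segment"))
  idx <- bandIndices(ps, lo, hi)
  if (mode == "weighted") {
    f <- frequencies(ps)[idx]
    p <- psd(ps)[idx]
    tot <- sum(p)
    if (tot <= 0)
      stop("frequency variance undefined: zero band power in band", call. = FALSE)
    w <- p / tot
    fbar <- sum(w * f)
    sum(w * (f - fbar)^2)
  } else {
    if (ncol(ps@segPsd) < 2L)
      stop("'peak_per_segment' mode needs at least 2 segments", call. = FALSE)
    if (all(ps@segPsd[idx, ] == 0))
      stop("frequency variance undefined: zero band power in band", call. = FALSE)
    peaks <- frequencies(ps)[idx][apply(ps@segPsd[idx, , drop = FALSE], 2L,
                                        which.max)]
    var(peaks)
  }
}

#' Gamma-band summary metrics of a power spectrum
#'
#' @param ps a [PowerSpectrum-class].
#' @param lo,hi gamma band limits in Hz (defaults from the spectrum config,
#'   falling back to 20-80 Hz).
#' @return a [GammaMetrics-class]: band power, peak frequency, frequency
#'   variance (normalized power is `NA` until [normalizeToControl()] output
#'   is attached by the caller).
#' @export
gammaMetrics <- function(ps, lo = NULL, hi = NULL) {
  if (!is(ps, "PowerSpectrum")) stop("'ps' must be a PowerSpectrum", call. = FALSE)
  if (is.null(lo)) lo <- if (!is.null(ps@config$bandLow)) ps@config$bandLow else 20
  if (is.null(hi)) hi <- if (!is.null(ps@config$bandHigh)) ps@config$bandHigh else 80
  idx <- bandIndices(ps, lo, hi)
  bp <- integrateBandPower(ps, lo, hi)
  pk <- frequencies(ps)[idx][which.max(psd(ps)[idx])]
  fv <- tryCatch(frequencyVariance(ps, lo, hi), error = function(e) NA_real_)
  new("GammaMetrics", bandPower = bp, peakFrequency = pk,
      frequencyVariance = fv, normalizedPower = NA_real_,
      band = c(lo, hi))
}

#' Normalize per-recording metrics to an age-matched control group
#'
#' Each value is divided by the mean of the control-group values, so the
#' control group itself normalizes to mean 1.
#'
#' @param values numeric metric values to normalize.
#' @param controlValues the same metric for the age-matched control group.
#' @return `values / mean(controlValues)`.
#' @export
#' @examples
#' normalizeToControl(c(1, 2), c(1, 2, 3))
normalizeToControl <- function(values, controlValues) {
  if (length(controlValues) == 0L)
    stop("control group is empty", call. = FALSE)
  m <- mean(controlValues)
  if (!is.finite(m) || m <= 0)
    stop("control-group mean must be positive (got ", format(m), ")",
         call. = FALSE)
  values / m
}
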