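# Template-based detection and quantification of postsynaptic currents
# (EPSC/IPSC amplitude and frequency). The detection statistic is the
# scaled-template criterion: at each lag the template is fitted to the trace
# by least squares with a free scale and offset, and the criterion is the
# fitted scale divided by the SD of the fit residual.

#' Build an event template from aligned snippets
#'
#' Pointwise mean of at least 20 representative event snippets (equal length,
#' aligned at onset), baseline-subtracted at the onset sample and scaled to
#' unit peak magnitude.
#'
#' @param snippets list of equal-length numeric vectors, or a matrix with one
#'   snippet per column; each aligned at the event onset.
#' @param samplingRate sampling rate in Hz.
#' @param polarity optionally force `"inward"`/`"outward"`; by default
#'   inferred from the sign of the averaged peak.
#' @return an [EventTemplate-class].
#' @export
buildTemplate <- function(snippets, samplingRate, polarity = NULL) {
  if (is.matrix(snippets)) snippets <- asplit(snippets, 2L)
  nEv <- length(snippets)
  if (nEv < 20L)
    stop(sprintf("a template requires at least 20 averaged representative events (got %d)",
                 nEv), call. = FALSE)
  len <- unique(lengths(snippets))
  if (length(len) != 1L)
    stop("all snippets must have equal length", call. = FALSE)
  if (len < 2L) stop("snippets must have length >= 2", call. = FALSE)
  avg <- rowMeans(do.call(cbind, snippets))
  avg <- avg - avg[1L]                      # onset-sample baseline
  pk <- max(abs(avg))
  if (pk == 0) stop("averaged template is identically zero", call. = FALSE)
  w <- avg / pk
  inferred <- if (w[which.max(abs(w))] < 0) "inward" else "outward"
  if (is.null(polarity)) polarity <- inferred
  assertChoice(polarity, "polarity", c("inward", "outward"))
  new("EventTemplate", waveform = w, samplingRate = as.numeric(samplingRate),
      nSourceEvents = as.integer(nEv), polarity = polarity)
}

#' Extract equal-length snippets from a trace at given onsets
#'
#' Convenience for template construction: cuts `length` samples starting at
#' each onset; onsets whose snippet would run past the trace end are dropped.
#'
#' @param ts a [TimeSeries-class].
#' @param onsets onset times in seconds.
#' @param length snippet length in samples.
#' @return list of numeric vectors.
#' @export
extractSnippets <- function(ts, onsets, length) {
  x <- samples(ts)
  fs <- samplingRate(ts)
  idx0 <- floor((onsets - startTime(ts)) * fs) + 1L
  keep <- idx0 >= 1L & (idx0 + length - 1L) <= base::length(x)
  lapply(idx0[keep], function(i) x[i:(i + length - 1L)])
}

# Sliding least-squares template fit; returns per-lag fitted scale and
# criterion (scale / residual SD). Shared between the first scan and the
# post-subtraction rescan.
templateScan <- function(y, tw) {
  L <- length(tw)
  N <- length(y)
  st <- sum(tw)
  st2 <- sum(tw^2)
  denom <- st2 - st^2 / L
  cy <- cumsum(y)
  cy2 <- cumsum(y^2)
  Sy <- cy[L:N] - c(0, cy[seq_len(N - L)])
  Sy2 <- cy2[L:N] - c(0, cy2[seq_len(N - L)])
  Syt <- convolve(y, tw, type = "filter")   # sliding dot product y[i..i+L-1].tw
  s <- (Syt - st * Sy / L) / denom
  cc <- (Sy - s * st) / L
  sse <- Sy2 + s^2 * st2 + L * cc^2 - 2 * s * Syt - 2 * cc * Sy + 2 * s * cc * st
  sse <- pmax(sse, 0)
  resSd <- sqrt(sse / (L - 1L))
  # guard degenerate windows: a perfect fit (zero residual) only counts when
  # the fitted scale is non-negligible relative to the trace scale
  ampEps <- 1e-9 * max(abs(y), 1e-300)
  crit <- ifelse(resSd > 0, s / resSd, ifelse(s > ampEps, Inf, -Inf))
  crit[s <= ampEps & resSd == 0] <- -Inf
  list(scale = s, criterion = crit)
}

# Peak picking: one candidate per contiguous supra-threshold run of the
# criterion (at the run's maximum), then greedy acceptance in order of
# decreasing criterion with a minimum separation.
pickPeaks <- function(crit, threshold, minSep, taken = integer(0)) {
  above <- crit >= threshold
  if (!any(above)) return(integer(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- mapply(function(s, e) s + which.max(crit[s:e]) - 1L,
                 starts[r$values], ends[r$values])
  sel <- integer(0)
  for (i in cand[order(crit[cand], decreasing = TRUE)]) {
    if (all(abs(i - c(taken, sel)) >= minSep)) sel <- c(sel, i)
  }
  sel
}

#' Detect synaptic events by sliding scaled-template matching
#'
#' At each lag the template is optimally scaled (with a free baseline offset)
#' to the trace window; the detection statistic is the fitted scale divided
#' by the SD of the fit residual. Lags where the statistic reaches
#' `criterionThreshold`, separated by at least one template rise time, are
#' events; the fitted scale is the event amplitude. After the first pass the
#' detected scaled templates are subtracted and the trace is re-scanned once,
#' recovering partially overlapping events.
#'
#' @param ts a voltage-clamp [TimeSeries-class] (pA).
#' @param template an [EventTemplate-class] at the same sampling rate.
#' @param criterionThreshold detection threshold on the criterion (default 3.5).
#' @param rescan logical; subtract detected events and re-scan once
#'   (default `TRUE`).
#' @return a [DetectedEvents-class].
#' @export
detectEvents <- function(ts, template, criterionThreshold = 3.5,
                         rescan = TRUE) {
  if (!is(ts, "TimeSeries")) stop("'ts' must be a TimeSeries", call. = FALSE)
  if (!is(template, "EventTemplate"))
    stop("'template' must be an EventTemplate", call. = FALSE)
  if (samplingRate(ts) != samplingRate(template))
    stop(sprintf("sampling rate mismatch: trace %g Hz vs template %g Hz",
                 samplingRate(ts), samplingRate(template)), call. = FALSE)
  assertScalar(criterionThreshold, "criterionThreshold", lower = 0,
               strictLower = TRUE)
  y <- samples(ts)
  tw <- templateWaveform(template)
  L <- length(tw)
  if (L >= length(y))
    stop("trace must be longer than the template", call. = FALSE)
  minSep <- max(1L, which.max(abs(tw)) - 1L)   # one template rise time
  scan1 <- templateScan(y, tw)
  sel <- pickPeaks(scan1$criterion, criterionThreshold, minSep)
  scales <- scan1$scale[sel]
  crits <- scan1$criterion[sel]
  if (rescan && length(sel)) {
    y2 <- y
    for (k in seq_along(sel)) {
      idx <- sel[k]:(sel[k] + L - 1L)
      y2[idx] <- y2[idx] - scales[k] * tw
    }
    scan2 <- templateScan(y2, tw)
    sel2 <- pickPeaks(scan2$criterion, criterionThreshold, minSep, taken = sel)
    if (length(sel2)) {
      sel <- c(sel, sel2)
      scales <- c(scales, scan2$scale[sel2])
      crits <- c(crits, scan2$criterion[sel2])
    }
  }
  ord <- order(sel)
  sel <- sel[ord]; scales <- scales[ord]; crits <- crits[ord]
  peakSign <- sign(tw[which.max(abs(tw))])
  new("DetectedEvents",
      times = startTime(ts) + (sel - 1L) / samplingRate(ts),
      amplitudes = scales * peakSign,
      criterion = crits, threshold = criterionThreshold,
      polarity = polarity(template))
}

#' Summary statistics of detected events
#'
#' @param ev a [DetectedEvents-class].
#' @param duration recording duration in seconds (> 0).
#' @return list with `meanAmplitude` (mean of |amplitudes| in pA; `NA` when
#'   no events were detected), `frequency` (events per second) and `n`.
#' @export
eventStatistics <- function(ev, duration) {
  if (!is(ev, "DetectedEvents")) stop("'ev' must be DetectedEvents", call. = FALSE)
  assertScalar(duration, "duration", lower = 0, strictLower = TRUE)
  n <- length(eventTimes(ev))
  list(meanAmplitude = if (n) mean(abs(eventAmplitudes(ev))) else NA_real_,
       frequency = n / duration,
       n = n)
}
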