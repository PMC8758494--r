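# Synthetic-data generators with known ground truth. These define the study
# conditions every estimator is validated against: a kainate-induced-style
# gamma LFP (jittered ~30 Hz carrier over 1/f background), von Mises
# phase-coupled spike trains, double-exponential postsynaptic-current traces,
# and full genotype x age cohorts.

#' Parameters of the synthetic gamma LFP generator
#'
#' The carrier is modeled as `A(t) * cos(phi(t))` with
#' `dphi/dt = 2*pi*(carrierFreq + x(t))`, where `x(t)` is a slow
#' Ornstein-Uhlenbeck frequency jitter; this gives a well-defined ground-truth
#' phase against which the Hilbert phase estimator can be scored. Amplitude
#' jitter is a second OU process acting as a fractional modulation, and the
#' background is 1/f^beta noise shaped between 0.5 Hz and Nyquist.
#'
#' Defaults emulate slice LFP recordings of pharmacologically induced gamma:
#' 60 s at 5 kHz, a 30 Hz carrier of 0.2 mV with moderate amplitude/frequency
#' jitter on a 1/f background.
#'
#' @param duration trace duration in seconds (> 0).
#' @param samplingRate sampling rate in Hz (>= 4 x `carrierFreq`).
#' @param carrierFreq center frequency of the gamma rhythm in Hz.
#' @param carrierAmp carrier amplitude in mV.
#' @param ampJitterSd SD of the fractional amplitude jitter (>= 0).
#' @param freqJitterSd SD of the instantaneous-frequency jitter in Hz (>= 0).
#' @param noiseExponent beta of the 1/f^beta background.
#' @param noiseAmp RMS amplitude of the background noise in mV (>= 0).
#' @param seed integer RNG seed; identical seeds give bit-identical traces.
#' @return a validated parameter list of class `GammaLfpParams`.
#' @export
#' @examples
#' p <- gammaLfpParams(duration = 2, noiseAmp = 0, ampJitterSd = 0, freqJitterSd = 0)
#' sim <- simulateGammaLfp(p)
#' var(samples(sim$lfp))  # ~ carrierAmp^2 / 2
gammaLfpParams <- function(duration = 60, samplingRate = 5000,
                           carrierFreq = 30, carrierAmp = 0.2,
                           ampJitterSd = 0.2, freqJitterSd = 1,
                           noiseExponent = 1, noiseAmp = 0.05, seed = 1L) {
  assertScalar(duration, "duration", lower = 0, strictLower = TRUE)
  assertScalar(samplingRate, "samplingRate", lower = 0, strictLower = TRUE)
  assertScalar(carrierFreq, "carrierFreq", lower = 0, strictLower = TRUE)
  if (samplingRate < 4 * carrierFreq)
    stop("'samplingRate' must be at least 4 x 'carrierFreq'", call. = FALSE)
  assertScalar(carrierAmp, "carrierAmp", lower = 0)
  assertScalar(ampJitterSd, "ampJitterSd", lower = 0)
  assertScalar(freqJitterSd, "freqJitterSd", lower = 0)
  assertScalar(noiseExponent, "noiseExponent", lower = 0)
  assertScalar(noiseAmp, "noiseAmp", lower = 0)
  assertScalar(seed, "seed", lower = 0, upper = 2^31 - 1)
  structure(list(duration = duration, samplingRate = samplingRate,
                 carrierFreq = carrierFreq, carrierAmp = carrierAmp,
                 ampJitterSd = ampJitterSd, freqJitterSd = freqJitterSd,
                 noiseExponent = noiseExponent, noiseAmp = noiseAmp,
                 seed = as.integer(seed)),
            class = "GammaLfpParams")
}

#' Simulate a gamma-band LFP trace with ground-truth phase
#'
#' @param params a [gammaLfpParams()] object.
#' @return list with elements `lfp` (a [TimeSeries-class], mV), `phase` (a
#'   [PhaseSeries-class] holding the true carrier phase at every sample,
#'   peak = 0 convention), and `params`.
#' @export
simulateGammaLfp <- function(params) {
  if (!inherits(params, "GammaLfpParams"))
    stop("'params' must be created with gammaLfpParams()", call. = FALSE)
  set.seed(params$seed)
  fs <- params$samplingRate
  n <- round(params$duration * fs)
  dt <- 1 / fs
  freqJit <- ouProcess(n, dt, params$freqJitterSd, tau = 0.5)
  phi <- 2 * pi * cumsum(params$carrierFreq + freqJit) * dt
  ampJit <- ouProcess(n, dt, params$ampJitterSd, tau = 0.2)
  amp <- params$carrierAmp * pmax(0, 1 + ampJit)
  noise <- oneOverFNoise(n, fs, params$noiseExponent, params$noiseAmp)
  x <- amp * cos(phi)
  if (length(noise) == n) x <- x + noise
  list(lfp = TimeSeries(x, fs, units = "mV", label = "simulated gamma LFP"),
       phase = PhaseSeries(wrapPhase(phi), fs),
       params = params)
}

#' Parameters of the von Mises phase-coupled spike generator
#'
#' @param meanRate mean firing rate in Hz (>= 0).
#' @param kappa von Mises concentration (>= 0); `kappa = 0` gives
#'   phase-uniform spiking.
#' @param mu preferred phase angle in radians, `(-pi, pi]` (peak = 0).
#' @param refractory absolute refractory period in seconds (>= 0).
#' @param seed integer RNG seed.
#' @return a validated parameter list of class `CouplingParams`.
#' @export
couplingParams <- function(meanRate = 12, kappa = 2, mu = 0,
                           refractory = 0.002, seed = 1L) {
  assertScalar(meanRate, "meanRate", lower = 0)
  assertScalar(kappa, "kappa", lower = 0)
  assertScalar(mu, "mu", lower = -pi, upper = pi, strictLower = TRUE)
  assertScalar(refractory, "refractory", lower = 0)
  if (meanRate * refractory >= 0.5)
    stop("'meanRate' x 'refractory' must be < 0.5 for the dead-time compensation to hold",
         call. = FALSE)
  assertScalar(seed, "seed", lower = 0, upper = 2^31 - 1)
  structure(list(meanRate = meanRate, kappa = kappa, mu = mu,
                 refractory = refractory, seed = as.integer(seed)),
            class = "CouplingParams")
}

#' Simulate a spike train phase-coupled to a gamma phase track
#'
#' An inhomogeneous Poisson process with intensity proportional to
#' `exp(kappa * cos(phase - mu))` is generated by thinning a homogeneous
#' Poisson process, then an absolute refractory period is enforced. The
#' intensity is renormalized on the realized phase track (and compensated for
#' refractory dead time) so the realized mean rate matches `meanRate`.
#'
#' @param phaseTrack a [PhaseSeries-class] with the true (or estimated)
#'   gamma phase at every sample.
#' @param params a [couplingParams()] object.
#' @return a [SpikeTrain-class].
#' @export
#' @examples
#' sim <- simulateGammaLfp(gammaLfpParams(duration = 5, seed = 2))
#' st <- simulateCoupledSpikes(sim$phase, couplingParams(kappa = 4, seed = 3))
#' nSpikes(st)
simulateCoupledSpikes <- function(phaseTrack, params) {
  if (!is(phaseTrack, "PhaseSeries"))
    stop("'phaseTrack' must be a PhaseSeries", call. = FALSE)
  if (!inherits(params, "CouplingParams"))
    stop("'params' must be created with couplingParams()", call. = FALSE)
  ph <- phases(phaseTrack)
  n <- length(ph)
  if (n == 0L) stop("empty phase track", call. = FALSE)
  fs <- samplingRate(phaseTrack)
  totalT <- n / fs
  if (params$meanRate == 0)
    return(SpikeTrain(numeric(0), totalT))
  set.seed(params$seed)
  lam <- exp(params$kappa * cos(ph - params$mu))
  lam <- lam * params$meanRate / mean(lam)
  if (params$refractory > 0)
    lam <- lam / (1 - params$meanRate * params$refractory)
  lamMax <- max(lam)
  nCand <- rpois(1L, lamMax * totalT)
  if (nCand == 0L) return(SpikeTrain(numeric(0), totalT))
  cand <- sort(runif(nCand, 0, totalT))
  idx <- pmin(n, floor(cand * fs) + 1L)
  keep <- runif(nCand) < lam[idx] / lamMax
  st <- cand[keep]
  if (params$refractory > 0 && length(st) > 1L) {
    out <- numeric(length(st))
    k <- 0L
    last <- -Inf
    for (t in st) {
      if (t - last >= params$refractory) {
        k <- k + 1L
        out[k] <- t
        last <- t
      }
    }
    st <- out[seq_len(k)]
  }
  SpikeTrain(st, totalT)
}

#' Parameters of the synthetic postsynaptic-current trace generator
#'
#' Events occur at Poisson times; each contributes an
#' `exp(-t/decayTau) - exp(-t/riseTau)` kernel scaled to unit peak, with
#' log-normally distributed amplitudes, on Gaussian baseline noise.
#' Defaults emulate voltage-clamp EPSC recordings (inward events, ~30 pA,
#' a few events per second).
#'
#' @param eventRate Poisson event rate in Hz (>= 0).
#' @param ampMean mean event amplitude in pA (> 0).
#' @param ampCv coefficient of variation of amplitudes (>= 0).
#' @param riseTau rise time constant in seconds (> 0).
#' @param decayTau decay time constant in seconds (> `riseTau`).
#' @param noiseSd Gaussian baseline noise SD in pA (>= 0).
#' @param duration trace duration in seconds (> 0).
#' @param samplingRate sampling rate in Hz.
#' @param polarity `"inward"` (negative-going) or `"outward"`.
#' @param seed integer RNG seed.
#' @return a validated parameter list of class `SynapticTraceParams`.
#' @export
synapticTraceParams <- function(eventRate = 5, ampMean = 30, ampCv = 0.3,
                                riseTau = 5e-4, decayTau = 5e-3,
                                noiseSd = 3, duration = 60,
                                samplingRate = 5000,
                                polarity = c("inward", "outward"),
                                seed = 1L) {
  polarity <- match.arg(polarity)
  assertScalar(eventRate, "eventRate", lower = 0)
  assertScalar(ampMean, "ampMean", lower = 0, strictLower = TRUE)
  assertScalar(ampCv, "ampCv", lower = 0)
  assertScalar(riseTau, "riseTau", lower = 0, strictLower = TRUE)
  assertScalar(decayTau, "decayTau", lower = 0, strictLower = TRUE)
  if (decayTau <= riseTau)
    stop("'decayTau' must be greater than 'riseTau'", call. = FALSE)
  assertScalar(noiseSd, "noiseSd", lower = 0)
  assertScalar(duration, "duration", lower = 0, strictLower = TRUE)
  assertScalar(samplingRate, "samplingRate", lower = 0, strictLower = TRUE)
  assertScalar(seed, "seed", lower = 0, upper = 2^31 - 1)
  structure(list(eventRate = eventRate, ampMean = ampMean, ampCv = ampCv,
                 riseTau = riseTau, decayTau = decayTau, noiseSd = noiseSd,
                 duration = duration, samplingRate = samplingRate,
                 polarity = polarity, seed = as.integer(seed)),
            class = "SynapticTraceParams")
}

#' Unit-peak difference-of-exponentials postsynaptic-current kernel
#'
#' @param riseTau rise time constant (s).
#' @param decayTau decay time constant (s), greater than `riseTau`.
#' @param samplingRate sampling rate (Hz).
#' @param lengthFactor kernel support as a multiple of `decayTau` (default 8).
#' @return numeric vector starting at the event onset, positive, peak = 1.
#' @export
pscKernel <- function(riseTau, decayTau, samplingRate, lengthFactor = 8) {
  if (decayTau <= riseTau) stop("'decayTau' must exceed 'riseTau'", call. = FALSE)
  tk <- seq(0, decayTau * lengthFactor, by = 1 / samplingRate)
  k <- exp(-tk / decayTau) - exp(-tk / riseTau)
  k / max(k)
}

#' Simulate a voltage-clamp trace of postsynaptic currents
#'
#' @param params a [synapticTraceParams()] object.
#' @return list with elements `trace` (a [TimeSeries-class], pA), `events`
#'   (data.frame of ground-truth `onset` seconds and signed `amplitude` pA)
#'   and `params`. Event onsets are kept at least one kernel length away from
#'   the trace end so no event is truncated.
#' @export
simulateSynapticTrace <- function(params) {
  if (!inherits(params, "SynapticTraceParams"))
    stop("'params' must be created with synapticTraceParams()", call. = FALSE)
  set.seed(params$seed)
  fs <- params$samplingRate
  n <- round(params$duration * fs)
  kern <- pscKernel(params$riseTau, params$decayTau, fs)
  sgn <- if (params$polarity == "inward") -1 else 1
  maxOnset <- max(0, params$duration - length(kern) / fs)
  nEv <- rpois(1L, params$eventRate * params$duration)
  onsets <- sort(runif(nEv, 0, maxOnset))
  if (params$ampCv > 0) {
    sdlog <- sqrt(log(1 + params$ampCv^2))
    amps <- rlnorm(nEv, log(params$ampMean) - sdlog^2 / 2, sdlog)
  } else {
    amps <- rep(params$ampMean, nEv)
  }
  x <- numeric(n)
  for (i in seq_len(nEv)) {
    i0 <- floor(onsets[i] * fs) + 1L
    idx <- i0:min(n, i0 + length(kern) - 1L)
    x[idx] <- x[idx] + sgn * amps[i] * kern[seq_along(idx)]
  }
  if (params$noiseSd > 0) x <- x + rnorm(n, sd = params$noiseSd)
  list(trace = TimeSeries(x, fs, units = "pA",
                          label = sprintf("simulated %s PSC trace", params$polarity)),
       events = data.frame(onset = onsets, amplitude = sgn * amps),
       params = params)
}

#' Render a spike train as a current-clamp voltage trace
#'
#' Places a stereotyped action-potential waveform (Gaussian depolarization
#' from baseline to peak) at each spike time on a noisy baseline, so the
#' amplitude-threshold spike detector can be exercised end to end.
#'
#' @param spikes a [SpikeTrain-class].
#' @param samplingRate sampling rate in Hz.
#' @param baseline resting membrane potential in mV.
#' @param peak AP peak in mV.
#' @param width AP half-width parameter (Gaussian sigma) in seconds.
#' @param noiseSd membrane noise SD in mV.
#' @param seed integer RNG seed.
#' @return a [TimeSeries-class] in mV spanning `duration(spikes)`.
#' @export
simulateApTrace <- function(spikes, samplingRate, baseline = -60, peak = 30,
                            width = 3e-4, noiseSd = 0.5, seed = 1L) {
  if (!is(spikes, "SpikeTrain")) stop("'spikes' must be a SpikeTrain", call. = FALSE)
  set.seed(as.integer(seed))
  fs <- samplingRate
  n <- round(duration(spikes) * fs)
  x <- rep(baseline, n)
  half <- ceiling(4 * width * fs)
  shape <- (peak - baseline) * exp(-((-half:half) / fs)^2 / (2 * width^2))
  for (t in spikeTimes(spikes)) {
    c0 <- round(t * fs) + 1L
    idx <- max(1L, c0 - half):min(n, c0 + half)
    x[idx] <- x[idx] + shape[idx - c0 + half + 1L]
  }
  if (noiseSd > 0) x <- x + rnorm(n, sd = noiseSd)
  TimeSeries(x, fs, units = "mV", label = "simulated current-clamp trace")
}

#' Define a genotype x age cohort design
#'
#' @param groups data.frame with columns `genotype`, `age`, `nCells`
#'   (one row per design cell, no duplicates, `nCells >= 1`).
#' @param effects named list keyed by `"genotype:age"`; each entry is a list
#'   of positive multipliers applied to the base parameters, among
#'   `carrierAmp`, `kappa`, `meanRate`, `ampMean`, `eventRate`. Missing
#'   entries/multipliers default to 1.
#' @param lfp base [gammaLfpParams()].
#' @param coupling base [couplingParams()].
#' @param synaptic base [synapticTraceParams()].
#' @param masterSeed integer master seed; per-cell seeds are derived
#'   deterministically from it.
#' @return a validated design list of class `CohortDesign`.
#' @export
cohortDesign <- function(groups, effects = list(),
                         lfp = gammaLfpParams(),
                         coupling = couplingParams(),
                         synaptic = synapticTraceParams(),
                         masterSeed = 1L) {
  if (!is.data.frame(groups) ||
      !all(c("genotype", "age", "nCells") %in% names(groups)))
    stop("'groups' must be a data.frame with columns genotype, age, nCells",
         call. = FALSE)
  key <- paste(groups$genotype, groups$age, sep = ":")
  if (anyDuplicated(key))
    stop("duplicate group labels in 'groups': ",
         paste(key[duplicated(key)], collapse = ", "), call. = FALSE)
  if (any(groups$nCells < 1)) stop("'nCells' must be >= 1 per group", call. = FALSE)
  unknown <- setdiff(names(effects), key)
  if (length(unknown))
    stop("effects refer to unknown groups: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (e in effects) {
    bad <- setdiff(names(e), c("carrierAmp", "kappa", "meanRate",
                               "ampMean", "eventRate"))
    if (length(bad))
      stop("unknown effect multiplier(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (any(unlist(e) <= 0)) stop("effect multipliers must be > 0", call. = FALSE)
  }
  stopifnot(inherits(lfp, "GammaLfpParams"),
            inherits(coupling, "CouplingParams"),
            inherits(synaptic, "SynapticTraceParams"))
  assertScalar(masterSeed, "masterSeed", lower = 0, upper = 2^31 - 1)
  structure(list(groups = groups, effects = effects, lfp = lfp,
                 coupling = coupling, synaptic = synaptic,
                 masterSeed = as.integer(masterSeed)),
            class = "CohortDesign")
}

effectMultiplier <- function(design, key, what) {
  e <- design$effects[[key]]
  if (is.null(e) || is.null(e[[what]])) 1 else e[[what]]
}

#' Simulate a full genotype x age cohort with known ground truth
#'
#' One record per cell: the simulated LFP and its true phase, a coupled spike
#' train, a synaptic-current trace with its ground-truth event list, the true
#' per-cell generator parameters, and the factor labels. Per-cell seeds are
#' derived deterministically from the master seed, so identical designs give
#' identical datasets.
#'
#' @param design a [cohortDesign()] object.
#' @param simulateSynaptic logical; set `FALSE` to skip the synaptic traces
#'   (faster when only coupling/power metrics are needed).
#' @return list of class `GammaCohort` with elements `cells` (list of
#'   per-cell records), `truth` (data.frame of true parameters per cell) and
#'   `design`.
#' @export
simulateCohort <- function(design, simulateSynaptic = TRUE) {
  if (!inherits(design, "CohortDesign"))
    stop("'design' must be created with cohortDesign()", call. = FALSE)
  cells <- list()
  truth <- list()
  for (g in seq_len(nrow(design$groups))) {
    row <- design$groups[g, ]
    key <- paste(row$genotype, row$age, sep = ":")
    for (ci in seq_len(row$nCells)) {
      seed <- deriveSeed(design$masterSeed, g, ci)
      lfpP <- design$lfp
      lfpP$carrierAmp <- lfpP$carrierAmp * effectMultiplier(design, key, "carrierAmp")
      lfpP$seed <- seed
      sim <- simulateGammaLfp(lfpP)
      cpP <- design$coupling
      cpP$kappa <- cpP$kappa * effectMultiplier(design, key, "kappa")
      cpP$meanRate <- cpP$meanRate * effectMultiplier(design, key, "meanRate")
      cpP$seed <- seed + 1L
      spikes <- simulateCoupledSpikes(sim$phase, cpP)
      syn <- NULL
      synP <- design$synaptic
      synP$ampMean <- synP$ampMean * effectMultiplier(design, key, "ampMean")
      synP$eventRate <- synP$eventRate * effectMultiplier(design, key, "eventRate")
      synP$seed <- seed + 2L
      if (simulateSynaptic) syn <- simulateSynapticTrace(synP)
      cellId <- sprintf("%s_%s_c%02d", row$genotype, row$age, ci)
      cells[[cellId]] <- list(
        cellId = cellId, genotype = as.character(row$genotype),
        age = as.character(row$age),
        lfp = sim$lfp, phase = sim$phase, spikes = spikes,
        synTrace = if (is.null(syn)) NULL else syn$trace,
        synEvents = if (is.null(syn)) NULL else syn$events,
        trueParams = list(lfp = lfpP, coupling = cpP, synaptic = synP))
      truth[[cellId]] <- data.frame(
        cellId = cellId, genotype = as.character(row$genotype),
        age = as.character(row$age), carrierAmp = lfpP$carrierAmp,
        kappa = cpP$kappa, mu = cpP$mu, meanRate = cpP$meanRate,
        ampMean = synP$ampMean, eventRate = synP$eventRate,
        seed = seed, stringsAsFactors = FALSE)
    }
  }
  structure(list(cells = cells, truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
                 design = design),
            class = "GammaCohort")
}
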