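# Phase-coupling module: zero-phase filtering, Hilbert phase, spike
# detection, circular statistics, Rayleigh gate, per-cell composition.

test_that("the band-pass filter is zero-phase on an in-band tone", {
  tone <- makeTone(30, duration = 10)
  filt <- bandpassFilter(tone)
  ix <- localMaxima(samples(tone)[10000:40000])
  iy <- localMaxima(samples(filt)[10000:40000])
  offsets <- vapply(ix, function(i) min(abs(iy - i)), numeric(1))
  expect_lte(max(offsets), 1)
})

test_that("stop-band attenuation matches the independent magnitude oracle", {
  # DC is eliminated
  dc <- TimeSeries(rep(2, 50000), 5000)
  expect_lt(rmsInterior(bandpassFilter(dc)), 1e-6 * 2)
  # 5 Hz: well below the pass band
  f5 <- bandpassFilter(makeTone(5, duration = 10))
  expect_lt(rmsInterior(f5), 0.05)
  expect_lt(rmsInterior(f5), max(10 * filterGain(5, 5000), 1e-4))
  # 18 Hz: transition band, quantitatively checked against the oracle
  f18 <- bandpassFilter(makeTone(18, duration = 10))
  ratio <- rmsInterior(f18) / rmsInterior(makeTone(18, duration = 10))
  theory <- filterGain(18, 5000)
  expect_lt(abs(ratio - theory) / theory, 0.2)
  # Nyquist violation is rejected
  expect_error(bandpassFilter(makeTone(30, fs = 60),
                              filterConfig(20, 40)), "Nyquist")
})

test_that("instantaneous phase follows the peak-0 / trough-pi convention", {
  tone <- makeTone(30, duration = 10)
  ph <- instantaneousPhase(tone)
  x <- samples(tone)
  p <- phases(ph)
  interior <- 5000:45000
  maxima <- intersect(localMaxima(x), interior)
  minima <- intersect(localMaxima(-x), interior)
  expect_lt(max(abs(p[maxima])), 0.05)
  expect_lt(max(abs(abs(p[minima]) - pi)), 0.05)
  # unwrapped phase strictly increases for a pure tone
  un <- cumsum(c(p[interior][1], wrapPhase(diff(p[interior]))))
  expect_true(all(diff(un) > 0))
  expect_error(instantaneousPhase(TimeSeries(rep(1, 100), 100)), "constant")
})

test_that("amplitude-threshold spike detection finds injected APs", {
  fs <- 5000
  trueTimes <- seq(0.5, 9.5, by = 1)
  st <- SpikeTrain(trueTimes, 10)
  trace <- simulateApTrace(st, fs, noiseSd = 0.5, seed = 4L)
  det <- detectSpikes(trace, spikeDetectConfig(threshold = 0))
  expect_identical(nSpikes(det), length(trueTimes))
  expect_lte(max(abs(spikeTimes(det) - trueTimes)), 1 / fs)
  # fully subthreshold trace
  flat <- TimeSeries(rnorm(5000, -60, 0.5), fs)
  expect_identical(nSpikes(detectSpikes(flat)), 0L)
})

test_that("double threshold crossings within one AP are merged", {
  fs <- 5000
  x <- rep(-60, 1000)
  # one AP whose noisy crest dips below threshold for 2 samples
  x[500:520] <- 20
  x[508:509] <- -1
  trace <- TimeSeries(x, fs)
  det <- detectSpikes(trace, spikeDetectConfig(threshold = 0,
                                               minInterval = 0.002))
  expect_identical(nSpikes(det), 1L)
  # without merging the same trace yields two events
  det0 <- detectSpikes(trace, spikeDetectConfig(threshold = 0, minInterval = 0))
  expect_identical(nSpikes(det0), 2L)
})

test_that("spike phase angles are read at the nearest sample", {
  tone <- makeTone(30, duration = 10)
  ph <- instantaneousPhase(tone)
  fs <- samplingRate(tone)
  peaks <- intersect(localMaxima(samples(tone)), 5000:45000)
  troughs <- intersect(localMaxima(-samples(tone)), 5000:45000)
  angP <- spikePhaseAngles(ph, SpikeTrain((peaks - 1) / fs, 10))
  angT <- spikePhaseAngles(ph, SpikeTrain((troughs - 1) / fs, 10))
  expect_lt(max(abs(angP)), 0.1)
  expect_lt(max(abs(abs(angT) - pi)), 0.1)
  expect_identical(spikePhaseAngles(ph, SpikeTrain(numeric(0), 10)),
                   numeric(0))
  shifted <- PhaseSeries(phases(ph), fs, t0 = 5)
  expect_error(spikePhaseAngles(shifted, SpikeTrain(0.1, 10)), "outside")
})

test_that("coupling statistics recover perfect, uniform and von Mises cases", {
  r <- couplingStatistics(rep(pi / 4, 50), duration = 10)
  expect_equal(vectorLength(r), 1)
  expect_equal(phaseAngle(r), pi / 4)
  expect_lt(rayleighP(r), 1e-10)
  expect_true(isIncluded(r))
  expect_equal(firingRate(r), 5)

  grid <- (0:99) * 2 * pi / 100
  expect_lt(vectorLength(couplingStatistics(grid, 10)), 1e-10)

  # von Mises sample, kappa = 2: vector length ~ I1(2)/I0(2)
  fs <- 5000
  t <- seq(0, 45 - 1 / fs, by = 1 / fs)
  track <- PhaseSeries(wrapPhase(2 * pi * 30 * t), fs)
  st <- simulateCoupledSpikes(track, couplingParams(meanRate = 23, kappa = 2,
                                                    refractory = 0, seed = 21L))
  ang <- wrapPhase(2 * pi * 30 * spikeTimes(st))[1:1000]
  expect_lt(abs(vectorLength(couplingStatistics(ang, 45)) - vonMisesVL(2)),
            0.03)
})

test_that("too few spikes give an excluded result, not an error", {
  r <- couplingStatistics(rep(0.2, 5), duration = 10)
  expect_false(isIncluded(r))
  expect_match(excludedReason(r), "n < n_min")
  expect_true(is.na(vectorLength(r)))
  expect_equal(firingRate(r), 0.5)
})

test_that("Rayleigh p values are calibrated and match a Monte Carlo null", {
  expect_lt(rayleighTest(rep(1.3, 30)), 1e-8)
  expect_error(rayleighTest(1), "at least 2")
  # size calibration under the uniform null
  withr::local_seed(7)
  rej <- mean(vapply(1:2000, function(i)
    rayleighTest(runif(50, -pi, pi)) < 0.05, logical(1)))
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.065)
  # the corrected-series p at n = 30, r = 0.3 vs a 1e5-draw null
  n <- 30; robs <- 0.3
  withr::local_seed(8)
  th <- matrix(runif(1e5 * n, -pi, pi), nrow = n)
  rnull <- sqrt(colSums(cos(th))^2 + colSums(sin(th))^2) / n
  pmc <- mean(rnull >= robs)
  # analytic p at the same n and r (only n and r enter the statistic)
  pan <- exp(-n * robs^2) * (1 + (2 * n * robs^2 - (n * robs^2)^2) / (4 * n) -
    (24 * n * robs^2 - 132 * (n * robs^2)^2 + 76 * (n * robs^2)^3 -
       9 * (n * robs^2)^4) / (288 * n^2))
  expect_lt(abs(pan - pmc) / pmc, 0.1)
})

test_that("analyzeCell composes the full chain with the inclusion gate", {
  sim <- simulateGammaLfp(gammaLfpParams(duration = 15, seed = 31L))
  stC <- simulateCoupledSpikes(sim$phase, couplingParams(meanRate = 20,
                                                         kappa = 4, seed = 32L))
  ct <- simulateApTrace(stC, 5000, seed = 33L)
  res <- analyzeCell(sim$lfp, ct)
  expect_true(isIncluded(res))
  expect_gt(vectorLength(res), 0.5)

  # uncoupled cell: not included in the clear majority of seeds
  incl <- vapply(1:20, function(s) {
    simU <- simulateGammaLfp(gammaLfpParams(duration = 15, seed = 400 + s))
    stU <- simulateCoupledSpikes(simU$phase,
                                 couplingParams(meanRate = 15, kappa = 0,
                                                seed = 500 + s))
    ctU <- simulateApTrace(stU, 5000, seed = 600 + s)
    isIncluded(analyzeCell(simU$lfp, ctU))
  }, logical(1))
  expect_lte(mean(incl), 0.10 + 1e-9)

  # spike-free cell trace: excluded with the n_min reason
  quiet <- TimeSeries(rnorm(length(samples(sim$lfp)), -60, 0.5), 5000)
  rq <- analyzeCell(sim$lfp, quiet)
  expect_match(excludedReason(rq), "n < n_min")

  # mismatched inputs are rejected
  expect_error(analyzeCell(sim$lfp, TimeSeries(1:10, 1000)), "sampling rate")
})

test_that("coupling results are invariant to LFP offset and equivariant to rotation", {
  sim <- simulateGammaLfp(gammaLfpParams(duration = 15, freqJitterSd = 0,
                                         seed = 41L))
  stC <- simulateCoupledSpikes(sim$phase, couplingParams(meanRate = 20,
                                                         kappa = 4, seed = 42L))
  ct <- simulateApTrace(stC, 5000, seed = 43L)
  base <- analyzeCell(sim$lfp, ct)
  # DC offset on the LFP changes nothing
  off <- TimeSeries(samples(sim$lfp) + 5, 5000, units = "mV")
  ro <- analyzeCell(off, ct)
  expect_equal(vectorLength(ro), vectorLength(base))
  expect_equal(phaseAngle(ro), phaseAngle(base))
  expect_equal(rayleighP(ro), rayleighP(base))
  # delaying all spikes by a quarter gamma cycle rotates the angle by ~pi/2
  quarter <- 1 / (4 * 30)
  stShift <- SpikeTrain(spikeTimes(stC) + quarter, duration(stC) + quarter)
  ctS <- simulateApTrace(stShift, 5000, seed = 43L)
  ctS <- TimeSeries(samples(ctS)[seq_along(samples(ct))], 5000)
  rs <- analyzeCell(sim$lfp, ctS)
  expect_lt(abs(vectorLength(rs) - vectorLength(base)), 0.02)
  dAng <- wrapPhase(phaseAngle(rs) - phaseAngle(base))
  expect_lt(abs(abs(dAng) - pi / 2), 0.15)
})
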