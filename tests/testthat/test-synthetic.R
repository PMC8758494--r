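# Synthetic-data generators: determinism, calibration, conservation.

test_that("noise-free gamma carrier has variance A^2/2 and peak-0 phase", {
  p <- gammaLfpParams(duration = 60, carrierAmp = 1, ampJitterSd = 0,
                      freqJitterSd = 0, noiseAmp = 0)
  sim <- simulateGammaLfp(p)
  x <- samples(sim$lfp)
  expect_lt(abs(mean(x^2) - mean(x)^2 - 0.5), 1e-6)
  # ground-truth phase convention: near-zero phase <-> near-maximal signal
  ph <- phases(sim$phase)
  expect_true(all(x[abs(ph) < 0.01] > 0.999))
  expect_true(all(x[abs(abs(ph) - pi) < 0.01] < -0.999))
})

test_that("gamma LFP generator is a pure function of its seed", {
  p <- gammaLfpParams(duration = 5, seed = 77L)
  a <- simulateGammaLfp(p)
  b <- simulateGammaLfp(p)
  expect_identical(samples(a$lfp), samples(b$lfp))
  expect_identical(phases(a$phase), phases(b$phase))
  c <- simulateGammaLfp(gammaLfpParams(duration = 5, seed = 78L))
  expect_false(identical(samples(a$lfp), samples(c$lfp)))
})

test_that("pure background noise has the requested 1/f^beta spectral slope", {
  beta <- 1.5
  p <- gammaLfpParams(duration = 120, samplingRate = 1000, carrierAmp = 0,
                      ampJitterSd = 0, freqJitterSd = 0,
                      noiseExponent = beta, noiseAmp = 1, seed = 5L)
  sim <- simulateGammaLfp(p)
  ps <- computePowerSpectrum(sim$lfp,
                             spectralConfig(segmentLength = 4096,
                                            analysisDuration = 120))
  f <- frequencies(ps)
  keep <- f >= 1 & f <= 100
  fit <- lm(log(psd(ps)[keep]) ~ log(f[keep]))
  expect_lt(abs(unname(coef(fit)[2]) + beta), 0.15)
})

test_that("generator parameter invariants are enforced", {
  expect_error(gammaLfpParams(duration = -1), "duration")
  expect_error(gammaLfpParams(carrierFreq = 30, samplingRate = 100), "4 x")
  expect_error(gammaLfpParams(ampJitterSd = -0.1), "ampJitterSd")
  expect_error(couplingParams(kappa = -1), "kappa")
  expect_error(synapticTraceParams(riseTau = 5e-3, decayTau = 5e-4), "decayTau")
  expect_error(synapticTraceParams(ampMean = 0), "ampMean")
})

test_that("uniform (kappa = 0) spiking has Poisson counts and uniform phases", {
  fs <- 1000
  t <- seq(0, 100 - 1 / fs, by = 1 / fs)
  track <- PhaseSeries(wrapPhase(2 * pi * 30 * t), fs)
  st <- simulateCoupledSpikes(track, couplingParams(meanRate = 10, kappa = 0,
                                                    seed = 42L))
  expect_lt(abs(nSpikes(st) - 1000), 3 * sqrt(1000))
  # calibration: Rayleigh should NOT reject for the vast majority of seeds
  pass <- vapply(1:500, function(s) {
    sti <- simulateCoupledSpikes(track, couplingParams(meanRate = 10,
                                                       kappa = 0, seed = s))
    rayleighTest(spikePhaseAngles(track, sti)) >= 0.05
  }, logical(1))
  expect_gte(mean(pass), 0.93)
})

test_that("coupled spiking concentrates phases at mu with the right mean rate", {
  fs <- 5000
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  track <- PhaseSeries(wrapPhase(2 * pi * 30 * t), fs)
  st <- simulateCoupledSpikes(track, couplingParams(meanRate = 15, kappa = 4,
                                                    mu = pi / 2, seed = 3L))
  expect_gt(nSpikes(st), 500)
  ang <- wrapPhase(2 * pi * 30 * spikeTimes(st))  # exact phase at spike times
  expect_lt(abs(circularMean(ang) - pi / 2), 0.1)
  # realized rate matches the requested 15 Hz x 40 s (3 SD + 2% tolerance)
  expect_lt(abs(nSpikes(st) - 600), 3 * sqrt(600) + 0.02 * 600)
  expect_true(all(diff(spikeTimes(st)) >= 0.002))
})

test_that("zero-rate and empty-phase-track cases behave as specified", {
  fs <- 1000
  track <- PhaseSeries(wrapPhase(2 * pi * 30 * seq(0, 1, by = 1 / fs)), fs)
  expect_identical(nSpikes(simulateCoupledSpikes(
    track, couplingParams(meanRate = 0, seed = 1L))), 0L)
  expect_error(PhaseSeries(numeric(0), fs), "length")
})

test_that("spike phases are von Mises distributed (KS calibration)", {
  kappa <- 2; mu <- 0.5
  fs <- 5000
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  track <- PhaseSeries(wrapPhase(2 * pi * 30 * t), fs)
  dens <- function(x) exp(kappa * cos(x - mu)) / (2 * pi * besselI(kappa, 0))
  grid <- seq(-pi, pi, length.out = 4001)
  cdfVals <- cumsum(dens(grid)) * diff(grid)[1]
  cdfVals <- cdfVals / max(cdfVals)
  vmCdf <- function(q) approx(grid, cdfVals, xout = q, rule = 2)$y
  pass <- vapply(1:10, function(s) {
    st <- simulateCoupledSpikes(track, couplingParams(meanRate = 34,
                                                      kappa = kappa, mu = mu,
                                                      refractory = 0, seed = s))
    ang <- wrapPhase(2 * pi * 30 * spikeTimes(st))
    n <- min(length(ang), 2000L)
    suppressWarnings(stats::ks.test(ang[seq_len(n)], vmCdf)$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(pass), 9L)
})

test_that("synaptic traces are the exact kernel sum plus noise", {
  p <- synapticTraceParams(eventRate = 3 / 60, ampMean = 20, ampCv = 0.3,
                           noiseSd = 0, duration = 60, seed = 42L)
  sim <- simulateSynapticTrace(p)
  ev <- sim$events
  expect_gt(nrow(ev), 0)
  # conservation: noiseless trace minus reconstructed event sum is zero
  kern <- pscKernel(p$riseTau, p$decayTau, p$samplingRate)
  recon <- numeric(length(samples(sim$trace)))
  for (i in seq_len(nrow(ev))) {
    i0 <- floor(ev$onset[i] * p$samplingRate) + 1L
    idx <- i0:(i0 + length(kern) - 1L)
    recon[idx] <- recon[idx] + ev$amplitude[i] * kern
  }
  expect_lt(max(abs(samples(sim$trace) - recon)), 1e-12)
  # unit-peak kernel: trace extremum within each event equals its amplitude
  for (i in seq_len(nrow(ev))) {
    i0 <- floor(ev$onset[i] * p$samplingRate) + 1L
    seg <- samples(sim$trace)[i0:(i0 + length(kern) - 1L)]
    expect_lt(abs(min(seg) - ev$amplitude[i]) / abs(ev$amplitude[i]), 0.01)
  }
})

test_that("event-free synaptic traces are pure noise at the requested SD", {
  p <- synapticTraceParams(eventRate = 0, noiseSd = 4, duration = 30, seed = 8L)
  sim <- simulateSynapticTrace(p)
  expect_identical(nrow(sim$events), 0L)
  expect_lt(abs(sd(samples(sim$trace)) - 4) / 4, 0.05)
})

test_that("synaptic event counts are Poisson around rate x duration", {
  p <- synapticTraceParams(eventRate = 2, duration = 60, seed = 11L)
  sim <- simulateSynapticTrace(p)
  expect_lt(abs(nrow(sim$events) - 120), 3 * sqrt(120))
})

test_that("cohort simulation is deterministic and respects the design", {
  groups <- data.frame(genotype = c("WT", "KI"), age = c("2", "2"),
                       nCells = c(1L, 1L))
  d <- cohortDesign(groups,
                    lfp = gammaLfpParams(duration = 2),
                    synaptic = synapticTraceParams(duration = 2),
                    masterSeed = 9L)
  a <- simulateCohort(d)
  b <- simulateCohort(d)
  expect_identical(length(a$cells), 2L)
  expect_identical(samples(a$cells[[1]]$lfp), samples(b$cells[[1]]$lfp))
  expect_identical(spikeTimes(a$cells[[2]]$spikes),
                   spikeTimes(b$cells[[2]]$spikes))
  expect_false(identical(samples(a$cells[[1]]$lfp), samples(a$cells[[2]]$lfp)))
  # duplicate design cells are rejected
  expect_error(cohortDesign(data.frame(genotype = c("WT", "WT"),
                                       age = c("2", "2"), nCells = 1L)),
               "duplicate")
  # effect multipliers must be positive and known
  expect_error(cohortDesign(groups, effects = list("WT:2" = list(kappa = 0))),
               "> 0")
  expect_error(cohortDesign(groups, effects = list("XX:9" = list(kappa = 1))),
               "unknown")
})

test_that("cohort effect multipliers reach the per-cell ground truth", {
  groups <- data.frame(genotype = c("WT", "KI"), age = c("2", "2"),
                       nCells = c(2L, 2L))
  d <- cohortDesign(groups, effects = list("KI:2" = list(kappa = 0.5)),
                    lfp = gammaLfpParams(duration = 2),
                    coupling = couplingParams(kappa = 4),
                    synaptic = synapticTraceParams(duration = 2),
                    masterSeed = 4L)
  ch <- simulateCohort(d, simulateSynaptic = FALSE)
  expect_identical(unique(ch$truth$kappa[ch$truth$genotype == "WT"]), 4)
  expect_identical(unique(ch$truth$kappa[ch$truth$genotype == "KI"]), 2)
})
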