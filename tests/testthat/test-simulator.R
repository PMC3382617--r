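test_that("no jitter and no noise give pure scaled copies of the signal", {
  cfg <- simConfig(nTrials = 12, nSamples = 128, sfreq = 250,
                   latencySd = 0, snr = Inf, seed = 3)
  sim <- simulateErp(cfg)
  expect_equal(epochData(sim), simClean(sim), tolerance = 1e-12)
  # every row is a scalar multiple of the base shape
  amp <- simTruth(sim)$amplitude[simTruth(sim)$peak == 1]
  base <- simClean(sim)[1, ] / amp[1]
  for (i in 2:12)
    expect_equal(simClean(sim)[i, ], base * amp[i], tolerance = 1e-10)
})

test_that("fixed condition shares draws across peaks, free does not", {
  simF <- simulateErp(simConfig(nTrials = 30, nSamples = 128, sfreq = 250,
                                condition = "fixed", seed = 5))
  trF <- simTruth(simF)
  expect_identical(trF$amplitude[trF$peak == 1], trF$amplitude[trF$peak == 2])
  expect_identical(trF$latency_shift_ms[trF$peak == 1],
                   trF$latency_shift_ms[trF$peak == 2])
  simI <- simulateErp(simConfig(nTrials = 30, nSamples = 128, sfreq = 250,
                                condition = "free", seed = 5))
  trI <- simTruth(simI)
  expect_false(isTRUE(all.equal(trI$amplitude[trI$peak == 1],
                                trI$amplitude[trI$peak == 2])))
})

test_that("draw statistics and realized SNR match the configuration", {
  sim <- simulateErp(simConfig(nTrials = 500, latencySd = 20, snr = 1,
                               seed = 11))
  lat <- simTruth(sim)$latency_shift_ms[simTruth(sim)$peak == 1]
  expect_lt(abs(sd(lat) - 20) / 20, 0.10)
  amp <- simTruth(sim)$amplitude
  expect_true(all(amp >= 0.5 & amp <= 2))
  expect_lt(abs(realizedSNR(simClean(sim), simNoise(sim)) - 1), 0.05)
})

test_that("AR noise has the requested autocorrelation structure", {
  wn <- arNoise(20, 400, numeric(0), sigma = 1, seed = 7)
  r1 <- cor(as.vector(wn[, -400]), as.vector(wn[, -1]))
  expect_lt(abs(r1), 3 / sqrt(20 * 400))
  ar1 <- arNoise(20, 1000, 0.8, sigma = 1, seed = 7)
  r1 <- cor(as.vector(ar1[, -1000]), as.vector(ar1[, -1]))
  expect_lt(abs(r1 - 0.8), 0.05)
  expect_error(arNoise(2, 100, c(1.2)), "stationary")
  expect_identical(arNoise(3, 50, c(0.5), seed = 9),
                   arNoise(3, 50, c(0.5), seed = 9))
})

test_that("realized SNR matches a double-loop RMS oracle", {
  set.seed(13)
  A <- matrix(rnorm(60), 6); N <- matrix(rnorm(60), 6)
  expect_equal(realizedSNR(A, A), 1, tolerance = 1e-12)
  expect_equal(realizedSNR(A, A / 2), 2, tolerance = 1e-12)
  sa <- 0; sn <- 0
  for (i in 1:6) for (j in 1:10) {
    sa <- sa + A[i, j]^2; sn <- sn + N[i, j]^2
  }
  expect_equal(realizedSNR(A, N), sqrt(sa / sn), tolerance = 1e-12)
  expect_equal(realizedSNR(A, N, power = TRUE), sa / sn, tolerance = 1e-12)
  expect_warning(r <- realizedSNR(A, matrix(0, 6, 10)), "infinite")
  expect_identical(r, Inf)
})

test_that("simulation is exactly reproducible from its seed", {
  s1 <- simulateErp(smallCfg(seed = 99))
  s2 <- simulateErp(smallCfg(seed = 99))
  expect_identical(epochData(s1), epochData(s2))
  m1 <- simulateFromModel(smallCfg(seed = 99))
  m2 <- simulateFromModel(smallCfg(seed = 99))
  expect_identical(epochData(m1), epochData(m2))
})

test_that("model-class generator satisfies its own fitted model exactly", {
  sim <- simulateFromModel(smallCfg(seed = 3, snr = 1e6,
                                    noise = NoiseSpec("white")))
  fit <- swaleFit(sim)
  # latency truth is recovered through rho = -a lambda at high SNR
  expect_gte(cor(latencyShifts(fit),
                 simTruth(sim)$latency_shift_ms), 0.999)
  expect_gte(cor(trialAmplitudes(fit), simTruth(sim)$amplitude), 0.999)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simConfig(ampLo = 0, ampHi = 2), "bounds")
  expect_error(simConfig(ampLo = 2, ampHi = 1), "bounds")
  expect_error(simConfig(peaks = data.frame(center_ms = 5000, width_ms = 40,
                                            polarity = 1,
                                            base_amplitude = 1)),
               "within the epoch")
  expect_error(NoiseSpec("ar", c(1.01)), "stationary")
})
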