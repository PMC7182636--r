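test_that("lead fields have the requested geometry, full row rank, and are reproducible", {
  lf <- makeLeadfield(64, 4000, seed = 1)
  expect_equal(dim(leadfieldMatrix(lf)), c(64L, 4000L))
  expect_identical(leadfieldMatrix(makeLeadfield(64, 4000, seed = 1)),
    leadfieldMatrix(lf))

  small <- makeLeadfield(8, 50, seed = 7)
  sv <- svd(leadfieldMatrix(small))$d
  expect_equal(sum(sv > max(sv) * 1e-10), 8L)
  # unit mean row norm; neighbouring columns correlated (smooth topographies)
  L <- leadfieldMatrix(small)
  expect_equal(mean(sqrt(rowSums(L^2))), 1)
  adj <- mean(vapply(1:49, function(v) cor(L[, v], L[, v + 1]), numeric(1)))
  expect_gt(adj, 0.5)

  expect_error(makeLeadfield(0, 10, seed = 1))
  expect_error(makeLeadfield(8, 4, seed = 1))
})

test_that("feature series are standardized AR(1) draws with the requested autocorrelation", {
  lag1 <- function(x) cor(x[-1], x[-length(x)])
  # Monte-Carlo over seeds
  ac0 <- mean(vapply(1:30, function(s) lag1(makeFeatureSeries(512, 0, s)), numeric(1)))
  expect_lt(abs(ac0), 3 / sqrt(512))
  ac8 <- mean(vapply(1:30, function(s) lag1(makeFeatureSeries(512, 0.8, s)), numeric(1)))
  expect_lt(abs(ac8 - 0.8), 0.1)

  x <- makeFeatureSeries(512, 0.5, seed = 2)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(sd(x), 1, tolerance = 1e-12)
  expect_identical(makeFeatureSeries(4, 0, seed = 5), makeFeatureSeries(4, 0, seed = 5))

  expect_error(makeFeatureSeries(512, 1, seed = 1))
  expect_error(makeFeatureSeries(512, -0.1, seed = 1))

  fs <- makeFeatureSet(64, seed = 3)
  expect_setequal(featureNames(fs),
    c("FluctuationCentroid", "FluctuationEntropy", "KeyClarity", "Mode", "PulseClarity"))
})

test_that("a noise-free single-network subject mixes to a rank-one sensor matrix", {
  nets <- list(plantedNetwork(25, 6, 10, "Mode"))
  scen <- scenario(8, 50, 32, 64, networks = nets, sensorNoiseSd = 0, seed = 3)
  sub <- simulateSubject(scen)
  sv <- svd(eegData(sub$recording))$d
  expect_equal(sum(sv > max(sv) * 1e-8), 1L)
})

test_that("the planted carrier dominates the sensor spectrum", {
  sub <- smallSubject()$sim
  x <- eegData(sub$recording)
  best <- which.max(rowSums(x^2))
  pg <- spec.pgram(ts(x[best, ], frequency = 64), spans = 9, plot = FALSE)
  peak <- pg$freq[which.max(pg$spec)]
  carriers <- vapply(sub$truth, `[[`, numeric(1), "carrier")
  expect_lt(min(abs(peak - carriers)), 0.5)
})

test_that("envelopes track their driving feature", {
  nets <- list(plantedNetwork(25, 6, 10, "Mode", coupling = 1, envelopeNoiseSd = 0.1))
  scen <- scenario(8, 50, 128, 64, networks = nets, sensorNoiseSd = 0, seed = 11)
  sub <- simulateSubject(scen)
  expect_gte(cor(sub$truth[[1]]$envelope, sub$truth[[1]]$feature), 0.9)
})

test_that("with zero noise the Hilbert envelope of the planted oscillation follows the feature", {
  nets <- list(plantedNetwork(25, 6, 10, "Mode", coupling = 1, envelopeNoiseSd = 0))
  scen <- scenario(8, 50, 128, 64, networks = nets, sensorNoiseSd = 0, seed = 11)
  sub <- simulateSubject(scen)
  x <- eegData(sub$recording)
  ch <- which.max(rowSums(x^2))
  # analytic-signal magnitude via FFT, smoothed over 1 s, sampled at 1 Hz
  n <- ncol(x)
  h <- c(1, rep(2, n / 2 - 1), 1, rep(0, n / 2 - 1))
  env <- Mod(fft(fft(x[ch, ]) * h, inverse = TRUE) / n)
  env <- stats::filter(env, rep(1 / 64, 64), sides = 2)
  sec <- env[seq(32, n - 32, by = 64)]
  feat <- sub$truth[[1]]$feature[seq_along(sec)]
  expect_gte(cor(sec, feat, use = "complete.obs"), 0.99)
})

test_that("sensor variance grows monotonically with coupling", {
  vars <- vapply(c(0.5, 1, 2), function(cp) {
    nets <- list(plantedNetwork(25, 6, 10, "Mode", coupling = cp, envelopeNoiseSd = 0))
    scen <- scenario(8, 50, 64, 64, networks = nets, sensorNoiseSd = 0.1, seed = 5)
    var(as.numeric(eegData(simulateSubject(scen)$recording)))
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
})

test_that("the scenario seed fixes the sensor data bit-for-bit", {
  scen <- smallSubject()$scen
  a <- simulateSubject(scen)
  b <- simulateSubject(scen)
  expect_identical(eegData(a$recording), eegData(b$recording))
})

test_that("carriers at or above Nyquist are rejected", {
  nets <- list(plantedNetwork(25, 6, 20, "Mode"))
  expect_error(scenario(8, 50, 32, 32, networks = nets), "Nyquist")
})

test_that("audio fixtures have the requested structure", {
  expect_identical(makeAudio("silence", 2), numeric(16000))
  expect_error(makeAudio("chirp", 2), "unknown audio kind")

  am <- makeAudio("amplitude-modulated-noise", 3, modRate = 4, seed = 2)
  fl <- fluctuationSpectrum(am, 8000)
  expect_lt(abs(fl$freqs[which.max(fl$amp)] - 4), 0.5)

  ct <- makeAudio("click-track", 3, bpm = 120)
  set.seed(8); wn <- rnorm(3 * 8000); wn <- wn / max(abs(wn))
  expect_gt(as.numeric(pulseClarity(ct, 8000)), as.numeric(pulseClarity(wn, 8000)))
})

test_that("WAV files round-trip through the PCM writer", {
  w <- makeAudio("key-tones", 0.5)
  path <- tempfile(fileext = ".wav")
  writeWavPcm16(w, 8000, path)
  back <- readWavPcm16(path)
  expect_equal(back$fs, 8000L)
  expect_equal(back$wave, w, tolerance = 1e-4)
  unlink(path)
})
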