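test_that("audio framing yields one frame per second with exact 1-s hops", {
  fs <- 1000
  wave <- seq_len(10 * fs)  # ramp encodes sample index
  fr <- frameAudio(wave, fs)
  expect_equal(ncol(fr), 10L)
  expect_equal(nrow(fr), 3 * fs)
  # center sample of frame k is sample (k - 0.5) * fs of the input
  mids <- fr[fs * 1.5 + 1, ]
  expect_equal(diff(mids), rep(fs, 9))  # hop exactly 1 s
  expect_equal(mids[2], 1.5 * fs + 1)

  expect_equal(ncol(frameAudio(rnorm(3 * fs), fs)), 3L)
  expect_error(frameAudio(numeric(0), fs), "empty")
})

test_that("a 512-s waveform frames into 512 feature samples", {
  fs <- 100
  fr <- frameAudio(rnorm(512 * fs), fs)
  expect_equal(ncol(fr), 512L)
})

test_that("fluctuation centroid and entropy have their closed-form values", {
  single <- list(freqs = c(2, 4, 6), amp = c(0, 5, 0))
  expect_equal(fluctuationCentroid(single), 4)
  expect_equal(fluctuationEntropy(single), 0)

  uniform <- list(freqs = seq(0.1, 10, length.out = 100), amp = rep(1, 100))
  expect_equal(fluctuationEntropy(uniform), log(100))

  two <- list(freqs = c(2, 6), amp = c(1, 1))
  expect_equal(fluctuationCentroid(two), 4)

  zero <- list(freqs = 1:5, amp = numeric(5))
  expect_equal(fluctuationCentroid(zero), 0)
  expect_equal(fluctuationEntropy(zero), 0)
  expect_error(fluctuationCentroid(list(freqs = 1, amp = -1)), "nonnegative")
})

test_that("the fluctuation spectrum localizes a 4-Hz modulation and is flat for plain noise", {
  fs <- 8000
  am <- makeAudio("amplitude-modulated-noise", 3, fs, modRate = 4, seed = 2)
  fl <- fluctuationSpectrum(am, fs)
  expect_lt(abs(fl$freqs[which.max(fl$amp)] - 4), 0.5)
  expect_true(all(fl$amp >= 0))

  set.seed(4)
  wn <- rnorm(3 * fs); wn <- wn / max(abs(wn))
  expect_gt(fluctuationEntropy(fluctuationSpectrum(wn, fs)), fluctuationEntropy(fl))

  sil <- fluctuationSpectrum(makeAudio("silence", 3, fs), fs)
  expect_true(all(sil$amp == 0))
})

test_that("key clarity and mode behave on profile, triad, and noise chroma", {
  kkMajorC <- c(6.35, 2.23, 3.48, 2.33, 4.38, 4.09, 2.52, 5.19, 2.39, 3.66, 2.29, 2.88)
  self <- chromaKeyMode(kkMajorC)
  expect_equal(as.numeric(self["keyClarity"]), 1)

  fs <- 8000
  maj <- keyMode(makeAudio("key-tones", 3, fs, key = "major"), fs)
  expect_gt(maj[["mode"]], 0)
  mino <- keyMode(makeAudio("key-tones", 3, fs, key = "minor"), fs)
  expect_lt(mino[["mode"]], 0)

  set.seed(4)
  wn <- rnorm(3 * fs); wn <- wn / max(abs(wn))
  expect_lt(keyMode(wn, fs)[["keyClarity"]], maj[["keyClarity"]])

  expect_equal(unname(chromaKeyMode(numeric(12))), c(0, 0))
  expect_equal(unname(keyMode(makeAudio("silence", 3, fs), fs)), c(0, 0))
})

test_that("pulse clarity finds the 120-BPM beat period and ranks fixtures sensibly", {
  fs <- 8000
  pc <- pulseClarity(makeAudio("click-track", 3, fs, bpm = 120), fs)
  expect_lt(abs(attr(pc, "bestLag") - 0.5), 0.05)
  expect_true(as.numeric(pc) >= 0 && as.numeric(pc) <= 1)

  expect_equal(as.numeric(pulseClarity(makeAudio("silence", 3, fs), fs)), 0)
  set.seed(4)
  wn <- rnorm(3 * fs); wn <- wn / max(abs(wn))
  expect_gt(as.numeric(pc), as.numeric(pulseClarity(wn, fs)))
})

test_that("all five features are invariant to global audio gain", {
  fs <- 8000
  w <- makeAudio("click-track", 6, fs, bpm = 100)
  f1 <- featureSeries(extractFeatures(w, fs))
  f2 <- featureSeries(extractFeatures(10 * w, fs))
  expect_equal(f1, f2, tolerance = 1e-8)
  expect_equal(ncol(f1), 6L)
})

test_that("feature CSV loading validates its schema", {
  fset <- makeFeatureSet(16, seed = 1)
  path <- tempfile(fileext = ".csv")
  writeFeaturesCSV(fset, path)
  back <- loadFeaturesCSV(path)
  expect_equal(featureSeries(back)[featureNames(fset), ], featureSeries(fset),
    tolerance = 1e-12)

  # 512-row table loads to a length-512 set
  big <- makeFeatureSet(512, seed = 2)
  writeFeaturesCSV(big, path)
  expect_equal(ncol(featureSeries(loadFeaturesCSV(path))), 512L)

  writeLines("", path)
  expect_error(loadFeaturesCSV(path))

  df <- as.data.frame(t(featureSeries(fset)))
  df$Tempo <- 1
  write.csv(df, path, row.names = FALSE)
  expect_error(loadFeaturesCSV(path), "Tempo")

  df$Tempo <- NULL
  df$Mode[3] <- NA
  write.csv(df, path, row.names = FALSE)
  expect_error(loadFeaturesCSV(path), "non-finite")
  unlink(path)
})
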