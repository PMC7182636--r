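test_that("the standard configuration yields 512 frames, 256 bins, 60 band bins", {
  set.seed(1)
  rec <- EEGRecording(matrix(rnorm(2 * 512 * 256), 2), fs = 256)
  tfr <- stftEEG(rec, frameS = 3, overlapS = 2, nfft = 512L)
  expect_equal(dim(tfr@coef), c(2L, 256L, 512L))
  expect_equal(range(frequencies(tfr)), c(0.5, 128))
  expect_equal(diff(frequencies(tfr))[1], 0.5)

  band <- selectBand(tfr, 1, 30)
  expect_equal(length(frequencies(band)), 60L)
  expect_equal(range(frequencies(band)), c(0.5, 30))
  # retained energy is a subset of the total
  expect_lte(sum(Mod(band@coef)^2), sum(Mod(tfr@coef)^2))
})

test_that("band selection keeps one guard bin below the low edge", {
  set.seed(2)
  rec <- EEGRecording(matrix(rnorm(32 * 64), 1), fs = 64)
  tfr <- stftEEG(rec, nfft = 128L)
  f <- frequencies(tfr)
  df <- f[2] - f[1]
  two <- selectBand(tfr, lo = 10, hi = 10 + df)
  expect_equal(frequencies(two), c(10 - df, 10, 10 + df))
  expect_error(selectBand(tfr, lo = 30, hi = 20))
})

test_that("a pure cosine concentrates at its bin and matches a direct DFT oracle", {
  fs <- 256
  t <- (0:(fs * 16 - 1)) / fs
  rec <- EEGRecording(matrix(cos(2 * pi * 10 * t), 1), fs = fs)
  tfr <- stftEEG(rec, nfft = 512L)
  k <- 8  # interior frame
  mag <- Mod(tfr@coef[1, , k])
  expect_equal(frequencies(tfr)[which.max(mag)], 10)

  # oracle: reflect-pad, window, truncate to the central 512 samples, direct DFT
  frameLen <- 3 * fs
  pad <- fs
  sig <- cos(2 * pi * 10 * t)
  padded <- c(rev(sig[2:(pad + 1)]), sig, rev(sig[(length(sig) - pad):(length(sig) - 1)]))
  start <- pad + round(((k - 0.5) - 1.5) * fs) + 1
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(frameLen - 1)) / (frameLen - 1))
  fr <- padded[start:(start + frameLen - 1)] * ham
  cut <- (frameLen - 512) %/% 2
  fr <- fr[(cut + 1):(cut + 512)]
  for (bin in c(10, 20, 41)) {  # 5 Hz, 10 Hz, 20.5 Hz
    oracle <- sum(fr * exp(-2i * pi * bin * (0:511) / 512))
    expect_lt(Mod(tfr@coef[1, bin, k] - oracle), 1e-8)
  }
})

test_that("the STFT is shift-covariant on the 1-s hop grid", {
  fs <- 64
  set.seed(3)
  x <- rnorm(10 * fs)
  y <- c(rep(0, fs), x[1:(9 * fs)])  # delayed by exactly 1 s
  ta <- stftEEG(EEGRecording(matrix(x, 1), fs = fs), nfft = 128L)
  tb <- stftEEG(EEGRecording(matrix(y, 1), fs = fs), nfft = 128L)
  # interior frames of the delayed signal equal the previous frames of x
  expect_equal(tb@coef[1, , 4:8], ta@coef[1, , 3:7], tolerance = 1e-10)
})

test_that("TFR projection matches a slice-by-slice loop oracle and is linear", {
  cf <- array(complex(real = rnorm(3 * 2 * 2), imaginary = rnorm(3 * 2 * 2)), c(3, 2, 2))
  tfr <- new("SensorTFR", coef = cf, freqs = c(1, 2), times = c(0.5, 1.5), window = "toy")
  G <- matrix(rnorm(15), 5, 3)
  inv <- new("InverseOperator", G = G, lambda2 = 0.1, depthGamma = 0)
  src <- projectTFR(tfr, inv)
  expect_equal(dim(src@coef), c(5L, 2L, 2L))
  for (f in 1:2) for (ti in 1:2)
    expect_equal(src@coef[, ti, f], (G %*% cf[, f, ti])[, 1], tolerance = 1e-12)

  zero <- projectTFR(new("SensorTFR", coef = array(0i, c(3, 2, 2)),
    freqs = c(1, 2), times = c(0.5, 1.5), window = "toy"), inv)
  expect_true(all(zero@coef == 0))

  ident <- new("InverseOperator", G = diag(3), lambda2 = 0, depthGamma = 0)
  same <- projectTFR(tfr, ident)
  expect_equal(same@coef, aperm(cf, c(1, 3, 2)), tolerance = 1e-12)
})

test_that("design-matrix unfolding is a lossless source-major bijection", {
  cf <- array(complex(real = rnorm(24), imaginary = rnorm(24)), c(4, 3, 2))
  src <- new("SourceTFR", coef = cf, freqs = c(1, 2), times = c(0.5, 1.5, 2.5))
  des <- buildDesignMatrix(src)
  expect_equal(dim(designMatrix(des)), c(3L, 8L))  # Nt x (Nf * Ns)
  # column (v-1)*Nf + f holds src[v, , f]
  for (v in c(1, 4)) for (f in 1:2)
    expect_equal(designMatrix(des)[, (v - 1) * 2 + f], cf[v, , f])
  back <- refoldDesignMatrix(des)
  expect_equal(back@coef, cf)
})

test_that("white-noise TFR energy scales linearly with recording length", {
  energy <- function(nSec, seed) {
    set.seed(seed)
    rec <- EEGRecording(matrix(rnorm(nSec * 64), 1), fs = 64)
    sum(Mod(stftEEG(rec, nfft = 128L)@coef)^2) / nSec
  }
  longE <- mean(vapply(1:8, function(s) energy(64, s), numeric(1)))
  shortE <- mean(vapply(1:8, function(s) energy(16, s + 100), numeric(1)))
  expect_lt(abs(longE / shortE - 1), 0.1)
})

test_that("recordings shorter than one frame are rejected", {
  expect_error(stftEEG(EEGRecording(matrix(rnorm(64), 1), fs = 64)), "shorter")
})
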