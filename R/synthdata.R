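# Synthetic generator: lead fields, 1-Hz feature series, ground-truthed EEG
# with planted frequency-specific networks, and audio fixtures.

canonicalFeatureNames <- function() {
  c("FluctuationCentroid", "FluctuationEntropy", "KeyClarity", "Mode", "PulseClarity")
}

ringDistance <- function(i, j, n) {
  d <- abs(i - j)
  pmin(d, n - d)
}

# circular Gaussian smoothing of each row along the source ring, via FFT;
# the Gaussian kernel's DFT is strictly positive so smoothing preserves rank
smoothRowsCircular <- function(M, sd) {
  n <- ncol(M)
  idx <- 0:(n - 1)
  d <- pmin(idx, n - idx)
  k <- exp(-d^2 / (2 * sd^2))
  k <- k / sum(k)
  kf <- stats::fft(k)
  t(apply(M, 1L, function(row) Re(stats::fft(stats::fft(row) * kf, inverse = TRUE) / n)))
}

#' Generate a synthetic lead field
#'
#' Random dipole-like sensor topographies smoothed along a 1-D source ring, so
#' neighbouring sources have correlated topographies (the ill-posedness a
#' minimum-norm inverse must handle) without any anatomical geometry. The
#' matrix has full row rank (the Gaussian smoothing kernel has a strictly
#' positive DFT) and is scaled to unit mean row norm.
#'
#' @param nChannels number of sensors (>= 2).
#' @param nSources number of source points (>= nChannels).
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @param smoothSd smoothing width along the ring, in source index units;
#'   default `nSources/50` (at least 2).
#' @return A [LeadField-class] with ring positions `1:nSources`.
#' @examples
#' lf <- makeLeadfield(8, 50, seed = 1)
#' dim(leadfieldMatrix(lf))
#' @export
makeLeadfield <- function(nChannels, nSources, seed, smoothSd = max(2, nSources / 50)) {
  if (nChannels < 2 || nSources < nChannels)
    stop("need nSources >= nChannels >= 2")
  set.seed(as.integer(seed))
  L <- matrix(stats::rnorm(nChannels * nSources), nChannels, nSources)
  L <- smoothRowsCircular(L, smoothSd)
  rn <- sqrt(rowSums(L^2))
  L <- L / mean(rn)
  LeadField(L, positions = seq_len(nSources))
}

#' Generate a standardized smooth feature series
#'
#' Length-n AR(1) series with lag-1 autocorrelation `rho`, exactly
#' standardized to mean 0 and unit variance. Emulates the slowly varying 1-Hz
#' musical feature time courses that drive the planted network envelopes.
#'
#' @param n series length (>= 2).
#' @param rho AR(1) coefficient in [0, 1).
#' @param seed integer seed.
#' @return numeric vector of length n.
#' @export
makeFeatureSeries <- function(n, rho, seed) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (n < 2) stop("n must be >= 2")
  set.seed(as.integer(seed))
  burn <- 100L
  e <- stats::rnorm(n + burn)
  x <- as.numeric(stats::filter(e, rho, method = "recursive"))
  x <- x[(burn + 1L):(burn + n)]
  as.numeric(scale(x))
}

#' Generate a full five-feature set
#'
#' One [makeFeatureSeries()] draw per canonical feature name, with seeds
#' derived deterministically from `seed`.
#'
#' @param n samples (seconds of stimulus).
#' @param rho AR(1) smoothness, default 0.9.
#' @param seed integer seed.
#' @return A [FeatureSet-class] at 1 Hz.
#' @export
makeFeatureSet <- function(n, rho = 0.9, seed = 1L) {
  nm <- canonicalFeatureNames()
  series <- t(vapply(seq_along(nm),
    function(i) makeFeatureSeries(n, rho, seed = as.integer(seed) + 101L * i),
    numeric(n)))
  rownames(series) <- nm
  FeatureSet(series, rate = 1)
}

# Gaussian spatial weight profile on the source ring: nonnegative, unimodal
networkWeights <- function(network, nSources) {
  d <- ringDistance(seq_len(nSources), network@centerSource, nSources)
  exp(-d^2 / (2 * network@spatialSd^2))
}

#' Simulate one synthetic subject
#'
#' For each planted network the amplitude envelope is
#' `e(t) = max(0, baseline + coupling * feature(t) + noise)` evaluated on the
#' 1-Hz feature grid and linearly interpolated to the sample grid; the source
#' signal `e(t) * sin(2*pi*f0*t + phi)` is spread over the network's Gaussian
#' spatial profile, mixed to the sensors through the lead field, and white
#' sensor noise is added. The returned ground truth stores, per network, the
#' spatial weights, carrier frequency, driving feature and the realized 1-Hz
#' envelope, so downstream stages can be scored by parameter recovery.
#'
#' @param scen a [Scenario-class].
#' @param leadfield optional [LeadField-class]; generated from the scenario
#'   seed when missing.
#' @param features optional [FeatureSet-class] at 1 Hz; generated when missing.
#' @return list with elements `recording` ([EEGRecording-class]), `leadfield`,
#'   `features`, and `truth` (one entry per network: `weights`, `carrier`,
#'   `envelope`, `featureName`, `feature`).
#' @export
simulateSubject <- function(scen, leadfield = NULL, features = NULL) {
  validObject(scen)
  nSec <- as.integer(round(scen@duration))
  n <- as.integer(round(scen@duration * scen@fs))
  if (is.null(leadfield))
    leadfield <- makeLeadfield(scen@nChannels, scen@nSources, seed = scen@seed)
  if (is.null(features))
    features <- makeFeatureSet(nSec, rho = scen@featureRho, seed = scen@seed + 7L)
  L <- leadfieldMatrix(leadfield)
  stopifnot(nrow(L) == scen@nChannels, ncol(L) == scen@nSources)

  set.seed(scen@seed + 1L)
  tGrid <- (0:(n - 1L)) / scen@fs
  featGrid <- (seq_len(nSec) - 0.5)  # frame-center convention of the 1-Hz series
  sensor <- matrix(0, scen@nChannels, n)
  truth <- vector("list", length(scen@networks))
  for (k in seq_along(scen@networks)) {
    nw <- scen@networks[[k]]
    if (nw@carrierFreq >= scen@fs / 2) stop("carrier frequency at or above Nyquist")
    f <- featureSeries(features)[nw@featureName, ]
    env1 <- pmax(0, nw@baseline + nw@coupling * f +
      stats::rnorm(nSec, sd = nw@envelopeNoiseSd))
    env <- stats::approx(featGrid, env1, xout = tGrid, rule = 2)$y
    phi <- stats::runif(1, 0, 2 * pi)
    s <- env * sin(2 * pi * nw@carrierFreq * tGrid + phi)
    w <- networkWeights(nw, scen@nSources)
    sensor <- sensor + outer(as.numeric(L %*% w), s)
    truth[[k]] <- list(weights = w, carrier = nw@carrierFreq, envelope = env1,
      featureName = nw@featureName, feature = f)
  }
  if (scen@sensorNoiseSd > 0)
    sensor <- sensor + matrix(stats::rnorm(length(sensor), sd = scen@sensorNoiseSd),
      nrow(sensor), ncol(sensor))
  list(recording = EEGRecording(sensor, fs = scen@fs),
    leadfield = leadfield, features = features, truth = truth)
}

#' Generate audio fixtures
#'
#' Deterministic mono waveforms with known rhythmic/tonal structure, used to
#' validate the musical feature extractors: amplitude-modulated noise (known
#' fluctuation rate), key tones (known key and mode), a click track (known
#' tempo) and silence.
#'
#' @param kind one of `"amplitude-modulated-noise"`, `"key-tones"`,
#'   `"click-track"`, `"silence"`.
#' @param duration length in seconds.
#' @param fs audio sampling rate, default 8000 Hz.
#' @param modRate modulation rate (Hz) for modulated noise.
#' @param bpm tempo for the click track.
#' @param key `"major"` or `"minor"` triad for the key tones.
#' @param seed seed for the noise kinds.
#' @return numeric waveform in [-1, 1], length `duration * fs`.
#' @export
makeAudio <- function(kind, duration, fs = 8000, modRate = 4, bpm = 120,
                      key = "major", seed = 1L) {
  n <- as.integer(round(duration * fs))
  tt <- (0:(n - 1L)) / fs
  w <- switch(kind,
    "silence" = numeric(n),
    "amplitude-modulated-noise" = {
      set.seed(as.integer(seed))
      stats::rnorm(n) * (1 + sin(2 * pi * modRate * tt)) / 2
    },
    "key-tones" = {
      # triad over two octaves with a couple of harmonics; A440 tuning
      base <- 261.626  # C4
      semis <- if (identical(key, "minor")) c(0, 3, 7) else c(0, 4, 7)
      freqs <- base * 2^(c(semis, semis + 12) / 12)
      out <- numeric(n)
      for (f0 in freqs)
        out <- out + sin(2 * pi * f0 * tt) + 0.5 * sin(2 * pi * 2 * f0 * tt) +
          0.25 * sin(2 * pi * 3 * f0 * tt)
      out / max(abs(out))
    },
    "click-track" = {
      out <- numeric(n)
      period <- 60 / bpm
      clickLen <- max(2L, as.integer(round(0.01 * fs)))
      starts <- as.integer(round(seq(0, duration - 0.01, by = period) * fs)) + 1L
      decay <- exp(-seq_len(clickLen) / (clickLen / 4))
      for (s in starts) {
        idx <- s:min(n, s + clickLen - 1L)
        out[idx] <- out[idx] + decay[seq_along(idx)]
      }
      out / max(abs(out))
    },
    stop("unknown audio kind: ", kind)
  )
  if (kind == "amplitude-modulated-noise") w <- w / max(abs(w))
  w
}

#' Write / read a 16-bit PCM mono WAV file
#'
#' Minimal RIFF/WAVE serialization for the audio fixtures (binary files are
#' only ever written to temporary locations by the tests).
#'
#' @param wave numeric waveform in [-1, 1].
#' @param fs sampling rate (Hz).
#' @param path output file path.
#' @return `writeWavPcm16` returns `path` invisibly; `readWavPcm16` returns
#'   `list(wave, fs)`.
#' @export
writeWavPcm16 <- function(wave, fs, path) {
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataBytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataBytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(dataBytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname writeWavPcm16
#' @export
readWavPcm16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file")
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("malformed WAV: no data chunk")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only mono PCM supported")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, "raw", n = sz - 8L))
    } else if (identical(id, "data")) {
      pcm <- readBin(con, integer(), n = sz / 2L, size = 2, endian = "little")
      return(list(wave = pcm / 32767, fs = fs))
    } else {
      invisible(readBin(con, "raw", n = sz))
    }
  }
}

#' Simulate a multi-subject study with shared planted networks
#'
#' All subjects listen to the same "stimulus": one shared [FeatureSet-class]
#' drives three planted frequency-specific networks at common locations — an
#' alpha network (10 Hz), a beta network (20 Hz) and a delta network (2 Hz),
#' centered at 20%, 60% and 90% of the source ring with width 5% of the ring
#' and driven by FluctuationCentroid, KeyClarity and Mode respectively.
#' Subject-level lead fields, noise realizations and oscillator phases differ
#' by derived seeds, so the shared spatial structure must be recovered by the
#' group analysis rather than being trivially identical.
#'
#' @param nSubjects number of subjects (default 14).
#' @param nChannels sensors per subject (default 32).
#' @param nSources source-ring size (default 500).
#' @param duration seconds per recording (default 512).
#' @param fs sampling rate (default 64 Hz; the 1-30 Hz analysis band fits
#'   under its Nyquist rate).
#' @param coupling,envelopeNoiseSd,sensorNoiseSd,featureRho generator levels
#'   (defaults 1, 0.2, 0.2, 0.9).
#' @param seed master seed; every per-subject seed derives from it.
#' @return list with `subjects` (list of [simulateSubject()] results),
#'   `features` (the shared [FeatureSet-class]), `networks` (the three
#'   [PlantedNetwork-class] objects) and `truthWeights` (list of the three
#'   spatial weight profiles).
#' @export
simulateStudy <- function(nSubjects = 14L, nChannels = 32L, nSources = 500L,
                          duration = 512, fs = 64, coupling = 1,
                          envelopeNoiseSd = 0.2, sensorNoiseSd = 0.2,
                          featureRho = 0.9, seed = 1L) {
  seed <- as.integer(seed)
  features <- makeFeatureSet(as.integer(round(duration)), rho = featureRho,
    seed = seed + 77L)
  networks <- list(
    plantedNetwork(round(nSources * 0.2), nSources * 0.05, 10, "FluctuationCentroid",
      coupling = coupling, envelopeNoiseSd = envelopeNoiseSd),
    plantedNetwork(round(nSources * 0.6), nSources * 0.05, 20, "KeyClarity",
      coupling = coupling, envelopeNoiseSd = envelopeNoiseSd),
    plantedNetwork(round(nSources * 0.9), nSources * 0.05, 2, "Mode",
      coupling = coupling, envelopeNoiseSd = envelopeNoiseSd))
  subjects <- lapply(seq_len(nSubjects), function(s) {
    scen <- scenario(nChannels, nSources, duration, fs, networks = networks,
      sensorNoiseSd = sensorNoiseSd, featureRho = featureRho,
      seed = seed + 1000L + s)
    simulateSubject(scen, features = features)
  })
  list(subjects = subjects, features = features, networks = networks,
    truthWeights = lapply(networks, networkWeights, nSources = nSources))
}
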