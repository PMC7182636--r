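# Long-term musical features on 3-s frames with 67% overlap (1-Hz series):
# fluctuation centroid/entropy, key clarity, mode, pulse clarity.

#' Slice audio into 3-s frames on a 1-s hop grid
#'
#' The nominal hop, `frame * (1 - overlapFrac)`, is rounded to exactly 1 s so
#' the feature series has one sample per second of audio. Frame k is centered
#' at (k - 0.5) s; the signal is reflect-padded at both edges so a D-second
#' input yields exactly `round(D)` frames.
#'
#' @param wave numeric waveform.
#' @param fs audio sampling rate (Hz).
#' @param frame frame length in seconds (default 3).
#' @param overlapFrac fractional overlap of adjacent frames (default 0.67).
#' @return numeric matrix, `frame*fs` rows x `round(D)` columns.
#' @export
frameAudio <- function(wave, fs, frame = 3, overlapFrac = 0.67) {
  if (length(wave) == 0L) stop("empty audio")
  if (fs <= 0 || frame * fs < 1) stop("invalid framing parameters")
  hop <- round(frame * (1 - overlapFrac))  # 1 s by construction
  stopifnot(hop == 1)
  nSec <- as.integer(round(length(wave) / fs))
  if (nSec < 1L) stop("audio shorter than one second")
  frameLen <- as.integer(round(frame * fs))
  pad <- as.integer(ceiling((frame / 2 - 0.5) * fs))
  n <- length(wave)
  left <- if (pad > 0) rev(wave[seq(2L, min(pad + 1L, n))]) else numeric(0)
  right <- if (pad > 0) rev(wave[seq(max(1L, n - pad), n - 1L)]) else numeric(0)
  if (length(left) < pad) left <- c(rep(0, pad - length(left)), left)
  if (length(right) < pad) right <- c(right, rep(0, pad - length(right)))
  padded <- c(left, wave, right)
  out <- matrix(0, frameLen, nSec)
  for (k in seq_len(nSec)) {
    start <- pad + as.integer(round(((k - 0.5) - frame / 2) * fs)) + 1L
    out[, k] <- padded[start:(start + frameLen - 1L)]
  }
  out
}

# short-window power spectrogram of one frame: rows = frequency bins,
# columns = envelope samples at rate fs/hop
frameSpectrogram <- function(x, fs, win = 256L, hop = 128L) {
  n <- length(x)
  if (n < win) { win <- 2^floor(log2(n)); hop <- win %/% 2L }
  starts <- seq(1L, n - win + 1L, by = hop)
  h <- 0.54 - 0.46 * cos(2 * pi * (0:(win - 1L)) / (win - 1L))
  seg <- vapply(starts, function(s) x[s:(s + win - 1L)] * h, numeric(win))
  sp <- Mod(stats::mvfft(seg))^2
  nf <- win %/% 2L
  list(power = sp[2:(nf + 1L), , drop = FALSE],
    freqs = (1:nf) * fs / win, rate = fs / hop)
}

# log-spaced band edges covering the spectrogram bins
logBands <- function(freqs, nBands = 10L, fmin = 50) {
  fmax <- max(freqs)
  edges <- exp(seq(log(fmin), log(fmax), length.out = nBands + 1L))
  lapply(seq_len(nBands), function(b) which(freqs >= edges[b] & freqs <= edges[b + 1L]))
}

#' Fluctuation spectrum of one frame
#'
#' Amplitude envelopes of >= 8 log-spaced sub-bands are Fourier transformed
#' (after demeaning, so the DC pedestal does not mask the rhythm peak) and
#' their amplitude spectra summed across bands, restricted to 0-10 Hz: the
#' global repartition of rhythm periodicities within the frame.
#'
#' @param x one audio frame (numeric vector).
#' @param fs audio sampling rate (Hz).
#' @param nBands number of log-spaced sub-bands (default 10).
#' @return list with `freqs` (Hz, excluding DC) and `amp` (nonnegative
#'   summed amplitude); all-zero `amp` for a silent frame.
#' @export
fluctuationSpectrum <- function(x, fs, nBands = 10L) {
  if (length(x) == 0L) stop("empty frame")
  sg <- frameSpectrogram(x, fs)
  m <- ncol(sg$power)
  df <- sg$rate / m
  keep <- which((1:(m %/% 2L)) * df <= 10)
  freqs <- keep * df
  if (all(sg$power == 0)) return(list(freqs = freqs, amp = numeric(length(keep))))
  bands <- logBands(sg$freqs, nBands)
  amp <- numeric(length(keep))
  for (b in bands) {
    if (length(b) == 0L) next
    env <- sqrt(colSums(sg$power[b, , drop = FALSE]))
    env <- env - mean(env)
    fa <- Mod(stats::fft(env))[keep + 1L]
    amp <- amp + fa
  }
  list(freqs = freqs, amp = amp)
}

#' Fluctuation centroid and entropy
#'
#' Centroid: amplitude-weighted mean frequency of the fluctuation spectrum
#' (the average rhythm periodicity, Hz). Entropy: Shannon entropy of the
#' spectrum normalized to a probability vector — 0 for a single-bin spectrum,
#' log(K) for a uniform one. Both are 0 by convention for a zero spectrum.
#'
#' @param spec list with `freqs` and nonnegative `amp`, as returned by
#'   [fluctuationSpectrum()].
#' @return A single numeric value.
#' @export
fluctuationCentroid <- function(spec) {
  if (any(spec$amp < 0)) stop("fluctuation spectrum must be nonnegative")
  s <- sum(spec$amp)
  if (s == 0) return(0)
  sum(spec$freqs * spec$amp) / s
}

#' @rdname fluctuationCentroid
#' @export
fluctuationEntropy <- function(spec) {
  if (any(spec$amp < 0)) stop("fluctuation spectrum must be nonnegative")
  s <- sum(spec$amp)
  if (s == 0) return(0)
  p <- spec$amp / s
  p <- p[p > 0]
  -sum(p * log(p))
}

# Krumhansl-Kessler key profiles (probe-tone ratings), tonic first
kkMajor <- c(6.35, 2.23, 3.48, 2.33, 4.38, 4.09, 2.52, 5.19, 2.39, 3.66, 2.29, 2.88)
kkMinor <- c(6.33, 2.68, 3.52, 5.38, 2.60, 3.53, 2.54, 4.75, 3.98, 2.69, 3.34, 3.17)

#' Chromagram of one frame
#'
#' Magnitude-squared FFT energy pooled into the 12 pitch classes over the
#' C2-B6 range, with bins assigned to the nearest equal-tempered semitone
#' (A440 tuning, +/- 50 cents).
#'
#' @param x one audio frame.
#' @param fs audio sampling rate (Hz).
#' @return numeric 12-vector (C, C#, ..., B).
#' @export
chromagram <- function(x, fs) {
  n <- 2^ceiling(log2(length(x)))
  X <- Mod(stats::fft(c(x, rep(0, n - length(x)))))^2
  nf <- n %/% 2L
  freqs <- (1:nf) * fs / n
  lo <- 65.406; hi <- 1975.5  # C2 .. B6
  sel <- which(freqs >= lo / 2^(0.5 / 12) & freqs <= hi * 2^(0.5 / 12))
  if (length(sel) == 0L) return(numeric(12))
  midi <- round(69 + 12 * log2(freqs[sel] / 440))
  pc <- (midi %% 12 + 9) %% 12  # midi 60 = C -> pitch class 0
  chroma <- numeric(12)
  for (k in 0:11) chroma[k + 1L] <- sum(X[sel][pc == k])
  chroma
}

#' Key clarity and mode from a chromagram
#'
#' The 12-bin chroma vector is correlated with the 24 Krumhansl-Kessler key
#' profiles (12 major + 12 minor rotations). Key clarity is the maximum
#' correlation; mode is the best-major minus best-minor correlation.
#'
#' @param chroma numeric 12-vector.
#' @return `c(keyClarity, mode)`; `c(0, 0)` for a silent chroma.
#' @export
chromaKeyMode <- function(chroma) {
  if (length(chroma) != 12L) stop("chroma must have 12 bins")
  if (all(chroma == 0) || stats::sd(chroma) == 0) return(c(keyClarity = 0, mode = 0))
  rot <- function(p, k) p[((0:11 - k) %% 12) + 1L]
  rMaj <- vapply(0:11, function(k) stats::cor(chroma, rot(kkMajor, k)), numeric(1))
  rMin <- vapply(0:11, function(k) stats::cor(chroma, rot(kkMinor, k)), numeric(1))
  c(keyClarity = max(rMaj, rMin), mode = max(rMaj) - max(rMin))
}

#' @rdname chromaKeyMode
#' @param x one audio frame; @param fs sampling rate (Hz).
#' @export
keyMode <- function(x, fs) chromaKeyMode(chromagram(x, fs))

# onset-strength envelope: half-wave-rectified first difference of
# log-compressed sub-band envelopes, summed over bands; the log floor is
# relative to the frame maximum so the result is invariant to global gain
onsetStrength <- function(sg, nBands = 10L) {
  bands <- logBands(sg$freqs, nBands)
  peak <- max(sg$power)
  if (peak == 0) return(list(onset = numeric(ncol(sg$power) - 1L), rate = sg$rate))
  floorVal <- 1e-6 * peak
  onset <- numeric(ncol(sg$power) - 1L)
  for (b in bands) {
    if (length(b) == 0L) next
    env <- log(colSums(sg$power[b, , drop = FALSE]) + floorVal)
    onset <- onset + pmax(0, diff(env))
  }
  list(onset = onset, rate = sg$rate)
}

#' Pulse clarity of one frame
#'
#' Normalized autocorrelation of the onset-strength envelope, maximized over
#' beat-period lags of 0.25-2 s (30-240 BPM), clamped to [0, 1]. Silence
#' returns 0. The best lag (s) is attached as attribute `"bestLag"`.
#'
#' @param x one audio frame.
#' @param fs audio sampling rate (Hz).
#' @return numeric in [0, 1].
#' @export
pulseClarity <- function(x, fs) {
  if (length(x) == 0L) stop("empty frame")
  sg <- frameSpectrogram(x, fs)
  os <- onsetStrength(sg)
  o <- os$onset - mean(os$onset)
  if (all(o == 0)) return(structure(0, bestLag = NA_real_))
  ac <- stats::acf(o, lag.max = min(length(o) - 1L, ceiling(2 * os$rate)),
    plot = FALSE, demean = FALSE)$acf[, 1, 1]
  lags <- (seq_along(ac) - 1L) / os$rate
  sel <- which(lags >= 0.25 & lags <= 2)
  if (length(sel) == 0L) return(structure(0, bestLag = NA_real_))
  i <- sel[which.max(ac[sel])]
  structure(max(0, min(1, ac[i])), bestLag = lags[i])
}

#' Extract the five long-term musical features
#'
#' Runs the frame-by-frame analysis ([frameAudio()], 3-s frames on the 1-s hop
#' grid) and computes FluctuationCentroid, FluctuationEntropy, KeyClarity,
#' Mode and PulseClarity per frame, yielding a 1-Hz [FeatureSet-class] with
#' one sample per second of audio.
#'
#' @param wave numeric waveform.
#' @param fs audio sampling rate (Hz).
#' @return A [FeatureSet-class], 5 x round(duration) at 1 Hz.
#' @export
extractFeatures <- function(wave, fs) {
  frames <- frameAudio(wave, fs)
  out <- matrix(0, 5L, ncol(frames),
    dimnames = list(canonicalFeatureNames(), NULL))
  for (k in seq_len(ncol(frames))) {
    x <- frames[, k]
    fl <- fluctuationSpectrum(x, fs)
    km <- keyMode(x, fs)
    out["FluctuationCentroid", k] <- fluctuationCentroid(fl)
    out["FluctuationEntropy", k] <- fluctuationEntropy(fl)
    out["KeyClarity", k] <- km[["keyClarity"]]
    out["Mode", k] <- km[["mode"]]
    out["PulseClarity", k] <- as.numeric(pulseClarity(x, fs))
  }
  FeatureSet(out, rate = 1)
}

#' Load a precomputed 1-Hz feature table from CSV
#'
#' The header must name exactly the five canonical features (an optional
#' `time_s` column is allowed); unknown columns and non-finite cells are
#' format errors.
#'
#' @param path CSV path with one row per second.
#' @return A [FeatureSet-class].
#' @export
loadFeaturesCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("feature CSV is empty")
  nm <- canonicalFeatureNames()
  cols <- setdiff(colnames(df), "time_s")
  extra <- setdiff(cols, nm)
  if (length(extra)) stop("unknown feature column(s): ", paste(extra, collapse = ", "))
  missing <- setdiff(nm, cols)
  if (length(missing)) stop("missing feature column(s): ", paste(missing, collapse = ", "))
  series <- t(as.matrix(df[, nm]))
  if (anyNA(series) || any(!is.finite(series))) stop("feature CSV contains non-finite cells")
  FeatureSet(series, rate = 1)
}

#' Write a FeatureSet to CSV (time_s + the five feature columns)
#'
#' @param fset a [FeatureSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeaturesCSV <- function(fset, path) {
  s <- featureSeries(fset)
  df <- data.frame(time_s = seq_len(ncol(s)) - 0.5, t(s), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
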