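# STFT tensor construction, band selection, source projection, and the
# unfolding into the ICA design matrix X0.

#' Short-time Fourier transform of a recording
#'
#' Hamming-windowed frames of `frameS` seconds on an exactly 1-s hop grid
#' (`frameS - overlapS`), reflect-padded at the edges so a D-second recording
#' yields `round(D)` frames — one complex spectrum per second. When the frame
#' holds more samples than `nfft` (3 s at 256 Hz = 768 samples vs. a 512-point
#' transform) the windowed frame is truncated to its central `nfft` samples,
#' which preserves the `fs/nfft` bin spacing implied by the transform length;
#' shorter frames are zero-padded. Only positive-frequency bins are kept.
#'
#' @param rec an [EEGRecording-class], at least one frame long.
#' @param frameS analysis window length in seconds (default 3).
#' @param overlapS overlap of adjacent windows in seconds (default 2).
#' @param nfft transform length (default 512).
#' @return A [SensorTFR-class] with `nfft/2` frequency bins spaced `fs/nfft`.
#' @export
stftEEG <- function(rec, frameS = 3, overlapS = 2, nfft = 512L) {
  fs <- samplingRate(rec)
  hop <- frameS - overlapS
  stopifnot(abs(hop - 1) < 1e-9)
  x <- eegData(rec)
  frameLen <- as.integer(round(frameS * fs))
  if (ncol(x) < frameLen) stop("recording shorter than one analysis frame")
  nfft <- as.integer(nfft)
  nt <- as.integer(round(ncol(x) / fs))
  nf <- nfft %/% 2L
  pad <- as.integer(ceiling((frameS / 2 - 0.5) * fs))
  n <- ncol(x)
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(frameLen - 1L)) / (frameLen - 1L))
  starts <- pad + vapply(seq_len(nt),
    function(k) as.integer(round(((k - 0.5) - frameS / 2) * fs)) + 1L, integer(1))
  if (frameLen > nfft) {
    cut0 <- (frameLen - nfft) %/% 2L
    keepIdx <- (cut0 + 1L):(cut0 + nfft)
  } else keepIdx <- NULL
  coef <- array(0i, dim = c(nrow(x), nf, nt))
  for (ch in seq_len(nrow(x))) {
    sig <- x[ch, ]
    left <- if (pad > 0) rev(sig[seq(2L, pad + 1L)]) else numeric(0)
    right <- if (pad > 0) rev(sig[seq(n - pad, n - 1L)]) else numeric(0)
    padded <- c(left, sig, right)
    frames <- vapply(starts, function(s) padded[s:(s + frameLen - 1L)] * ham,
      numeric(frameLen))
    if (!is.null(keepIdx)) {
      frames <- frames[keepIdx, , drop = FALSE]
    } else if (frameLen < nfft) {
      frames <- rbind(frames, matrix(0, nfft - frameLen, ncol(frames)))
    }
    F <- stats::mvfft(frames)
    coef[ch, , ] <- F[2:(nf + 1L), , drop = FALSE]
  }
  new("SensorTFR", coef = coef, freqs = (1:nf) * fs / nfft,
    times = seq_len(nt) - 0.5,
    window = sprintf("hamming %gs frame, %gs overlap, %d-point FFT", frameS, overlapS, nfft))
}

#' Restrict a TFR to an analysis band
#'
#' Keeps the bins with `lo - df <= f <= hi` where `df` is the bin spacing:
#' one guard bin below the nominal low edge, so the conventional 1-30 Hz
#' request at 0.5-Hz spacing retains exactly 60 bins (0.5 ... 30.0 Hz).
#'
#' @param tfr a [SensorTFR-class].
#' @param lo,hi band edges in Hz (defaults 1 and 30).
#' @return The band-limited [SensorTFR-class].
#' @export
selectBand <- function(tfr, lo = 1, hi = 30) {
  f <- frequencies(tfr)
  if (!(lo < hi) || hi > max(f) + 1e-9) stop("need lo < hi <= max frequency")
  df <- f[2] - f[1]
  keep <- which(f >= lo - df - 1e-9 & f <= hi + 1e-9)
  if (length(keep) == 0L) stop("empty band selection")
  new("SensorTFR", coef = tfr@coef[, keep, , drop = FALSE], freqs = f[keep],
    times = tfr@times, window = tfr@window)
}

#' Project a sensor TFR to source space
#'
#' Applies the inverse operator to every time-frequency slice, producing the
#' complex source-space tensor (sources x times x frequencies). Linear in the
#' input.
#'
#' @param tfr a [SensorTFR-class].
#' @param inv an [InverseOperator-class] matching the channel count.
#' @return A [SourceTFR-class].
#' @export
projectTFR <- function(tfr, inv) {
  d <- dim(tfr@coef)
  G <- inverseMatrix(inv)
  if (d[1] != ncol(G)) stop("channel count mismatch between TFR and inverse operator")
  flat <- tfr@coef
  dim(flat) <- c(d[1], d[2] * d[3])
  src <- G %*% flat                    # Ns x (Nf*Nt)
  dim(src) <- c(nrow(G), d[2], d[3])   # Ns x Nf x Nt
  src <- aperm(src, c(1, 3, 2))        # Ns x Nt x Nf
  new("SourceTFR", coef = src, freqs = tfr@freqs, times = tfr@times)
}

#' Unfold a source TFR into the ICA design matrix
#'
#' X0 has one row per time window and `Nf * Ns` columns in source-major order:
#' column `(v-1)*Nf + f` holds the coefficients of source `v` at frequency bin
#' `f`. The unfolding is a bijection; [refoldDesignMatrix()] inverts it
#' losslessly.
#'
#' @param src a [SourceTFR-class].
#' @return A [FourierDesign-class].
#' @export
buildDesignMatrix <- function(src) {
  d <- dim(src@coef)                   # Ns x Nt x Nf
  X <- aperm(src@coef, c(2, 3, 1))     # Nt x Nf x Ns
  dim(X) <- c(d[2], d[3] * d[1])
  new("FourierDesign", X0 = X, freqs = src@freqs, nSources = as.integer(d[1]),
    times = src@times)
}

#' @rdname buildDesignMatrix
#' @param design a [FourierDesign-class].
#' @export
refoldDesignMatrix <- function(design) {
  nf <- length(design@freqs)
  ns <- design@nSources
  nt <- nrow(design@X0)
  X <- design@X0
  dim(X) <- c(nt, nf, ns)
  new("SourceTFR", coef = aperm(X, c(3, 1, 2)), freqs = design@freqs,
    times = design@times)
}
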