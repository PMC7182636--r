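# EEG conditioning: common-average reference, zero-phase notch/band-pass with
# down-sampling, and the differentiate / median-filter / reintegrate DC-jump
# repair.

#' Common-average re-reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so the
#' channel mean is zero at each sample.
#'
#' @param rec an [EEGRecording-class] with at least two channels.
#' @return The re-referenced [EEGRecording-class].
#' @export
rereferenceCommonAverage <- function(rec) {
  x <- eegData(rec)
  if (nrow(x) < 2L) stop("common-average reference needs at least 2 channels")
  x <- sweep(x, 2L, colMeans(x))
  EEGRecording(x, fs = samplingRate(rec), channels = channelLabels(rec))
}

# zero-phase application of a filter to each row
filtfiltRows <- function(flt, x) {
  t(apply(x, 1L, function(row) signal::filtfilt(flt, row)))
}

#' Notch + band-pass filtering and down-sampling
#'
#' Zero-phase (forward-backward) 4th-order Butterworth high- and low-pass
#' filters with a Butterworth band-stop notch, followed by decimation to
#' `fsOut`. Forward-backward application squares the magnitude response, so
#' the effective roll-off is 8th order with no group delay — the component
#' time courses stay aligned with the stimulus clock. The low-pass cutoff
#' doubles as the anti-alias filter; `fsOut` must divide the input rate.
#'
#' @param rec an [EEGRecording-class].
#' @param notch notch center frequency in Hz (e.g. 50), or `NULL` to skip.
#' @param hp high-pass cutoff (Hz).
#' @param lp low-pass cutoff (Hz).
#' @param fsOut output sampling rate (Hz); `NULL` keeps the input rate.
#' @param notchHalfWidth half-width of the band-stop design (Hz, default 2).
#' @return Filtered, down-sampled [EEGRecording-class].
#' @export
filterChain <- function(rec, notch = 50, hp = 1, lp = 30, fsOut = NULL,
                        notchHalfWidth = 2) {
  fs <- samplingRate(rec)
  if (is.null(fsOut)) fsOut <- fs
  if (!(hp < lp)) stop("need hp < lp")
  if (lp >= fsOut / 2) stop("low-pass cutoff must be below the output Nyquist rate")
  if (fsOut > fs) stop("fsOut cannot exceed the input rate")
  x <- eegData(rec)
  if (!is.null(notch)) {
    if (notch >= fs / 2) stop("notch frequency above Nyquist")
    bs <- signal::butter(2, c(notch - notchHalfWidth, notch + notchHalfWidth) / (fs / 2),
      type = "stop")
    x <- filtfiltRows(bs, x)
  }
  hpF <- signal::butter(4, hp / (fs / 2), type = "high")
  lpF <- signal::butter(4, lp / (fs / 2), type = "low")
  x <- filtfiltRows(lpF, filtfiltRows(hpF, x))
  if (fsOut < fs) {
    fac <- fs / fsOut
    if (abs(fac - round(fac)) > 1e-9) stop("fs / fsOut must be an integer factor")
    x <- x[, seq(1L, ncol(x), by = as.integer(round(fac))), drop = FALSE]
  }
  EEGRecording(x, fs = fsOut, channels = channelLabels(rec))
}

#' Repair DC jumps by differentiate / median-filter / reintegrate
#'
#' The series is differentiated; first-difference samples whose magnitude
#' exceeds `thresh` (discontinuity spikes) are replaced by a running-median
#' estimate of the local slope; the result is cumulatively summed with the
#' original first sample restored. Smooth inputs whose slopes stay below the
#' threshold pass through unchanged (up to float rounding).
#'
#' @param x single-channel numeric vector.
#' @param kernel odd median-filter window length (>= 3), default 9.
#' @param thresh discontinuity threshold on |diff|; default 10x the median
#'   absolute first difference.
#' @return Repaired vector, same length as `x`.
#' @export
removeDCJumps <- function(x, kernel = 9L, thresh = NULL) {
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L || kernel < 3L) stop("kernel must be odd and >= 3")
  if (length(x) < 2L) return(x)
  d <- diff(x)
  if (is.null(thresh)) thresh <- 10 * stats::median(abs(d))
  med <- stats::runmed(d, kernel, endrule = "median")
  bad <- abs(d) > thresh
  d[bad] <- med[bad]
  c(x[1], x[1] + cumsum(d))
}

#' Apply the DC-jump repair to every channel of a recording
#'
#' @inheritParams removeDCJumps
#' @param rec an [EEGRecording-class].
#' @return The repaired [EEGRecording-class].
#' @export
removeDCJumpsRecording <- function(rec, kernel = 9L, thresh = NULL) {
  x <- t(apply(eegData(rec), 1L, removeDCJumps, kernel = kernel, thresh = thresh))
  EEGRecording(x, fs = samplingRate(rec), channels = channelLabels(rec))
}

#' Read a channels-by-samples matrix from CSV as an EEGRecording
#'
#' Plain-text ingestion: one row per channel, optional first column of channel
#' labels, no header.
#'
#' @param path CSV path.
#' @param fs sampling rate of the stored data (Hz).
#' @return An [EEGRecording-class].
#' @export
readEEGcsv <- function(path, fs) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  labels <- NULL
  if (!is.numeric(raw[[1]]) && all(is.na(suppressWarnings(as.numeric(raw[[1]]))))) {
    labels <- as.character(raw[[1]])
    raw <- raw[, -1, drop = FALSE]
  }
  EEGRecording(as.matrix(raw), fs = fs, channels = labels)
}
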