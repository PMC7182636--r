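# Component summaries: spatial power map with top-5% support, spectrum over
# the supported source points, and the envelope time course.

#' Spatial power map and top-5% support of one component
#'
#' The component row is refolded to its Nf x Ns matrix; the spatial power of
#' source v is the mean squared Fourier magnitude over frequency bins. The
#' support mask marks the `ceil(0.05 * Ns)` points at or above the 95th
#' percentile, with ties broken by lowest index so the count is exact and the
#' mask deterministic.
#'
#' @param sRow complex vector of length Nf*Ns (source-major).
#' @param nf,ns frequency-bin and source counts.
#' @param frac support fraction (default 0.05).
#' @return list with `power` (length Ns) and logical `mask`.
#' @export
spatialPowerMap <- function(sRow, nf, ns, frac = 0.05) {
  if (length(sRow) != nf * ns) stop("row length must equal Nf * Ns")
  mat <- matrix(sRow, nf, ns)
  power <- colMeans(Mod(mat)^2)
  ncap <- ceiling(frac * ns)
  ord <- order(power, decreasing = TRUE)   # stable: ties keep ascending index
  mask <- logical(ns)
  mask[ord[seq_len(ncap)]] <- TRUE
  list(power = power, mask = mask)
}

#' Power spectrum of one component over its spatial support
#'
#' `spectrum(f)` is the mean of `|s(f, v)|^2` over the masked source points.
#'
#' @param sRow complex vector of length Nf*Ns.
#' @param mask logical support mask of length Ns (nonempty).
#' @param nf,ns dimensions of the refold.
#' @return nonnegative numeric vector of length Nf.
#' @export
componentSpectrum <- function(sRow, mask, nf, ns) {
  if (!any(mask)) stop("empty support mask")
  mat <- matrix(sRow, nf, ns)
  rowMeans(Mod(mat[, mask, drop = FALSE])^2)
}

#' Envelope time course of one component
#'
#' Elementwise modulus of column k of the mixing matrix: the fluctuation of
#' the component's Fourier amplitude across the 1-s windows. Invariant to the
#' phase indeterminacy of the column.
#'
#' @param A complex mixing matrix (Nt x order) or a [FourierICAFit-class].
#' @param k component index.
#' @return nonnegative numeric vector of length Nt.
#' @export
componentTimecourse <- function(A, k) {
  if (is(A, "FourierICAFit")) A <- mixingMatrix(A)
  if (k < 1 || k > ncol(A)) stop("component index out of range")
  Mod(A[, k])
}

#' Summarize all components of a decomposition
#'
#' @param fit a [FourierICAFit-class].
#' @param subject subject identifier attached to each summary.
#' @param frac support fraction for the spatial mask.
#' @return list with one entry per component: `power`, `mask`, `spectrum`,
#'   `timecourse`, `peakFreq` (Hz at the spectrum argmax), `subject`,
#'   `component`.
#' @export
summarizeComponents <- function(fit, subject = 1L, frac = 0.05) {
  nf <- length(frequencies(fit))
  ns <- fit@nSources
  S <- sourceMatrix(fit)
  lapply(seq_len(nrow(S)), function(k) {
    pm <- spatialPowerMap(S[k, ], nf, ns, frac = frac)
    spec <- componentSpectrum(S[k, ], pm$mask, nf, ns)
    list(power = pm$power, mask = pm$mask, spectrum = spec,
      timecourse = componentTimecourse(fit, k),
      peakFreq = frequencies(fit)[which.max(spec)],
      subject = subject, component = k)
  })
}
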