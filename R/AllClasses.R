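#' @import methods
NULL

#' Multichannel EEG recording
#'
#' Container for a continuous multichannel EEG record: a channels-by-samples
#' real matrix in microvolts together with its sampling rate and channel
#' labels. All conditioning operations ([rereferenceCommonAverage()],
#' [filterChain()], [removeDCJumps()]) consume and return this class.
#'
#' @slot data numeric matrix, channels x samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot channels character vector of channel labels, one per row.
#'
#' @seealso [EEGRecording()] for the constructor.
#' @export
setClass("EEGRecording",
  representation(data = "matrix", fs = "numeric", channels = "character"))

setValidity("EEGRecording", function(object) {
  if (!is.numeric(object@data)) return("data must be a numeric matrix")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    return("data contains NA or non-finite values")
  if (length(object@fs) != 1L || object@fs <= 0) return("fs must be a single positive number")
  if (length(object@channels) != nrow(object@data))
    return("channel label count must equal the number of rows")
  TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate (Hz).
#' @param channels optional channel labels; defaults to `"ch1"`, `"ch2"`, ...
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(200), 2), fs = 100)
#' nChannels(rec)
#' @export
EEGRecording <- function(data, fs, channels = NULL) {
  data <- as.matrix(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  new("EEGRecording", data = data, fs = as.numeric(fs), channels = as.character(channels))
}

#' Lead field (forward model)
#'
#' Gain matrix L (channels x sources) mapping unit current at each cortical
#' source point to the sensor array, plus optional 1-D ring coordinates of the
#' source points (used by the synthetic generator's geometry).
#'
#' @slot L numeric matrix, Nc x Ns.
#' @slot positions numeric vector of source coordinates (possibly empty).
#' @export
setClass("LeadField", representation(L = "matrix", positions = "numeric"))

setValidity("LeadField", function(object) {
  if (any(!is.finite(object@L))) return("lead field has non-finite entries")
  if (ncol(object@L) < nrow(object@L)) return("need at least as many sources as channels")
  if (length(object@positions) && length(object@positions) != ncol(object@L))
    return("positions length must match the source count")
  TRUE
})

#' @rdname LeadField-class
#' @param L channels x sources gain matrix.
#' @param positions optional source coordinates.
#' @return A [LeadField-class] object.
#' @export
LeadField <- function(L, positions = numeric(0)) {
  new("LeadField", L = as.matrix(L), positions = as.numeric(positions))
}

#' Minimum-norm inverse operator
#'
#' The regularized linear inverse G (sources x channels) derived from a lead
#' field by [computeInverseOperator()], together with the regularization and
#' depth-weighting parameters it was built with.
#'
#' @slot G numeric matrix, Ns x Nc.
#' @slot lambda2 regularization parameter (applied after trace normalization).
#' @slot depthGamma depth-weighting exponent.
#' @export
setClass("InverseOperator",
  representation(G = "matrix", lambda2 = "numeric", depthGamma = "numeric"))

setValidity("InverseOperator", function(object) {
  if (any(!is.finite(object@G))) return("G has non-finite entries")
  if (object@lambda2 < 0) return("lambda2 must be nonnegative")
  TRUE
})

#' Sensor-space time-frequency representation
#'
#' Complex STFT coefficients of a multichannel recording arranged as a
#' channels x frequencies x times array, with the frequency and time grids and
#' a descriptor of the analysis window.
#'
#' @slot coef complex array, Nc x Nf x Nt.
#' @slot freqs strictly increasing frequency grid (Hz).
#' @slot times frame-center times (s), 1-s hop grid.
#' @slot window character descriptor of the framing.
#' @export
setClass("SensorTFR",
  representation(coef = "array", freqs = "numeric", times = "numeric", window = "character"))

setValidity("SensorTFR", function(object) {
  d <- dim(object@coef)
  if (length(d) != 3L) return("coef must be a 3-way array")
  if (length(object@freqs) != d[2]) return("freqs length must match dim 2")
  if (length(object@times) != d[3]) return("times length must match dim 3")
  if (is.unsorted(object@freqs, strictly = TRUE)) return("freqs must be strictly increasing")
  TRUE
})

#' Source-space time-frequency representation
#'
#' Complex STFT tensor after projection through an inverse operator, arranged
#' sources x times x frequencies (the layout consumed by
#' [buildDesignMatrix()]).
#'
#' @slot coef complex array, Ns x Nt x Nf.
#' @slot freqs frequency grid (Hz).
#' @slot times frame-center times (s).
#' @export
setClass("SourceTFR",
  representation(coef = "array", freqs = "numeric", times = "numeric"))

setValidity("SourceTFR", function(object) {
  d <- dim(object@coef)
  if (length(d) != 3L) return("coef must be a 3-way array")
  if (length(object@times) != d[2]) return("times length must match dim 2")
  if (length(object@freqs) != d[3]) return("freqs length must match dim 3")
  TRUE
})

#' Unfolded ICA design matrix
#'
#' The source-space STFT tensor unfolded to a two-way complex matrix X0 with
#' one row per time window and one column per (source, frequency) pair, in
#' source-major order: all Nf bins of source 1, then source 2, and so on.
#'
#' @slot X0 complex matrix, Nt x (Nf * Ns).
#' @slot freqs frequency grid (Hz), length Nf.
#' @slot nSources number of source points Ns.
#' @slot times frame-center times (s), length Nt.
#' @export
setClass("FourierDesign",
  representation(X0 = "matrix", freqs = "numeric", nSources = "integer", times = "numeric"))

setValidity("FourierDesign", function(object) {
  if (!is.complex(object@X0)) return("X0 must be complex")
  if (ncol(object@X0) != length(object@freqs) * object@nSources)
    return("column count must equal Nf * Ns")
  if (length(object@times) != nrow(object@X0)) return("times length must match row count")
  TRUE
})

#' Complex Fourier-ICA decomposition
#'
#' Result of unmixing a [FourierDesign-class]: a complex mixing matrix A
#' (Nt x order) whose column moduli are the component envelope time courses,
#' and a complex source matrix S (order x Nf*Ns) whose rows are
#' spatial-spectral patterns with unit variance. The whitening pair and the
#' removed row means are retained so that `A %*% S` reconstructs the rank-order
#' part of the centered design matrix.
#'
#' @slot A complex mixing matrix, Nt x order.
#' @slot S complex source matrix, order x (Nf*Ns).
#' @slot whitener,dewhitener complex whitening pair from [complexPCA()].
#' @slot rowMeans complex row means removed before whitening.
#' @slot eigvals all covariance eigenvalues (descending).
#' @slot freqs frequency grid; @slot nSources source count (row layout of S).
#' @slot nIter FastICA iterations used; @slot converged convergence flag.
#' @slot seed integer seed of the FastICA initialization.
#' @export
setClass("FourierICAFit",
  representation(A = "matrix", S = "matrix", whitener = "matrix",
    dewhitener = "matrix", rowMeans = "complex", eigvals = "numeric",
    freqs = "numeric", nSources = "integer", nIter = "integer",
    converged = "logical", seed = "integer"))

setValidity("FourierICAFit", function(object) {
  if (ncol(object@A) != nrow(object@S)) return("order of A and S disagree")
  if (length(object@freqs) * object@nSources != ncol(object@S) && object@nSources > 0L)
    return("S column count must equal Nf * Ns")
  TRUE
})

#' 1-Hz stimulus feature set
#'
#' The five long-term musical features as a features x time matrix sampled at
#' 1 Hz. Row names are the feature names; the canonical set is
#' FluctuationCentroid, FluctuationEntropy, KeyClarity, Mode, PulseClarity.
#'
#' @slot series features x time numeric matrix.
#' @slot rate sampling rate, 1 Hz by construction.
#' @export
setClass("FeatureSet", representation(series = "matrix", rate = "numeric"))

setValidity("FeatureSet", function(object) {
  if (anyNA(object@series)) return("feature series contain NA")
  if (is.null(rownames(object@series))) return("feature rows must be named")
  if (length(object@rate) != 1L || object@rate <= 0) return("rate must be positive")
  TRUE
})

#' @rdname FeatureSet-class
#' @param series features x time matrix with row names.
#' @param rate sampling rate in Hz (default 1).
#' @return A [FeatureSet-class] object.
#' @export
FeatureSet <- function(series, rate = 1) {
  new("FeatureSet", series = as.matrix(series), rate = as.numeric(rate))
}

#' ICASSO stability report
#'
#' Pooled components from repeated FastICA runs, their magnitude-correlation
#' similarity, the average-linkage partition into `order` clusters, the Iq
#' stability index per cluster, centrotype indices, and the representative
#' decomposition assembled from the centrotypes.
#'
#' @slot nRuns number of converged runs pooled.
#' @slot similarity pooled x pooled absolute-correlation matrix in [0,1].
#' @slot partition integer cluster id per pooled component.
#' @slot iq per-cluster stability index.
#' @slot centrotypes pooled index of each cluster's representative.
#' @slot representative [FourierICAFit-class] rebuilt from the centrotypes.
#' @export
setClass("StabilityReport",
  representation(nRuns = "integer", similarity = "matrix", partition = "integer",
    iq = "numeric", centrotypes = "integer", representative = "FourierICAFit"))

#' Stimulus-correlation screening result
#'
#' Component-by-feature Pearson correlations, the Monte-Carlo familywise
#' threshold used, and the retained (component, feature) pairs.
#'
#' @slot r components x features correlation matrix.
#' @slot rCrit familywise critical |r|.
#' @slot retained data.frame with columns component, feature, r.
#' @slot alpha nominal familywise level.
#' @slot nSurrogates surrogate draws behind rCrit.
#' @slot seed surrogate seed.
#' @export
setClass("CorrelationResult",
  representation(r = "matrix", rCrit = "numeric", retained = "data.frame",
    alpha = "numeric", nSurrogates = "integer", seed = "integer"))

#' Group-level spatial cluster result
#'
#' k-means partition of z-scored spatial maps pooled across subjects, with the
#' MDL-selected order, per-cluster retention flags (majority-subject rule) and
#' summaries (centroid map, pairwise map-correlation statistics, per-feature
#' subject counts, member spectra).
#'
#' @slot M number of clusters.
#' @slot assignment cluster id per retained component.
#' @slot centroids M x Ns centroid maps (z-score units).
#' @slot kept logical retention flag per cluster.
#' @slot summaries list of per-cluster summaries (see [summarizeCluster()]).
#' @slot subjects subject id per retained component.
#' @export
setClass("ClusterResult",
  representation(M = "integer", assignment = "integer", centroids = "matrix",
    kept = "logical", summaries = "list", subjects = "integer"))

#' Planted oscillatory network description
#'
#' Ground-truth generative unit for the synthetic data generator: a compact
#' Gaussian spatial profile on the source ring, a narrowband carrier, and an
#' amplitude envelope that follows one named 1-Hz stimulus feature linearly
#' (plus noise) above a baseline, rectified at zero.
#'
#' @slot centerSource index of the profile center on the source ring.
#' @slot spatialSd profile width in ring distance units.
#' @slot carrierFreq carrier frequency (Hz), within the 1-30 Hz analysis band.
#' @slot featureName name of the driving feature.
#' @slot coupling linear gain from standardized feature to envelope.
#' @slot baseline envelope offset keeping rectification rare (default 2).
#' @slot envelopeNoiseSd sd of the 1-Hz envelope noise.
#' @export
setClass("PlantedNetwork",
  representation(centerSource = "integer", spatialSd = "numeric",
    carrierFreq = "numeric", featureName = "character", coupling = "numeric",
    baseline = "numeric", envelopeNoiseSd = "numeric"))

setValidity("PlantedNetwork", function(object) {
  if (object@carrierFreq < 1 || object@carrierFreq > 30)
    return("carrierFreq must lie in the analyzed 1-30 Hz band")
  if (object@spatialSd <= 0) return("spatialSd must be positive")
  TRUE
})

#' @rdname PlantedNetwork-class
#' @param centerSource,spatialSd,carrierFreq,featureName,coupling,baseline,envelopeNoiseSd
#'   see the class slots.
#' @return A [PlantedNetwork-class] object.
#' @export
plantedNetwork <- function(centerSource, spatialSd, carrierFreq, featureName,
                           coupling = 1, baseline = 2, envelopeNoiseSd = 0.2) {
  new("PlantedNetwork", centerSource = as.integer(centerSource),
    spatialSd = as.numeric(spatialSd), carrierFreq = as.numeric(carrierFreq),
    featureName = as.character(featureName), coupling = as.numeric(coupling),
    baseline = as.numeric(baseline), envelopeNoiseSd = as.numeric(envelopeNoiseSd))
}

#' Synthetic recording scenario
#'
#' Full description of one synthetic subject: geometry, duration, sampling
#' rate, the planted networks, sensor noise level, and the seed that fixes all
#' randomness bit-for-bit.
#'
#' @slot nChannels,nSources geometry of the lead field.
#' @slot duration recording length (s); must be a whole number of seconds.
#' @slot fs sampling rate (Hz).
#' @slot networks list of [PlantedNetwork-class] objects.
#' @slot sensorNoiseSd additive white sensor noise sd.
#' @slot featureRho lag-1 autocorrelation of the generated 1-Hz features.
#' @slot seed integer seed.
#' @export
setClass("Scenario",
  representation(nChannels = "integer", nSources = "integer", duration = "numeric",
    fs = "numeric", networks = "list", sensorNoiseSd = "numeric",
    featureRho = "numeric", seed = "integer"))

setValidity("Scenario", function(object) {
  if (object@nChannels < 2L) return("need at least 2 channels")
  if (object@nSources < object@nChannels) return("need nSources >= nChannels")
  if (abs(object@duration - round(object@duration)) > 1e-9)
    return("duration must be an integer number of seconds (1-Hz feature grid)")
  if (object@fs <= 0) return("fs must be positive")
  ok <- vapply(object@networks, is, logical(1), class2 = "PlantedNetwork")
  if (length(ok) && !all(ok)) return("networks must be PlantedNetwork objects")
  for (nw in object@networks)
    if (nw@carrierFreq >= object@fs / 2)
      return("carrier frequency at or above Nyquist")
  TRUE
})

#' @rdname Scenario-class
#' @param nChannels,nSources,duration,fs,networks,sensorNoiseSd,featureRho,seed
#'   see the class slots.
#' @return A [Scenario-class] object.
#' @export
scenario <- function(nChannels, nSources, duration, fs, networks = list(),
                     sensorNoiseSd = 0.2, featureRho = 0.9, seed = 1L) {
  new("Scenario", nChannels = as.integer(nChannels), nSources = as.integer(nSources),
    duration = as.numeric(duration), fs = as.numeric(fs), networks = networks,
    sensorNoiseSd = as.numeric(sensorNoiseSd), featureRho = as.numeric(featureRho),
    seed = as.integer(seed))
}
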