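# Accessor generics and show methods for the core containers.

#' @rdname EEGRecording-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname EEGRecording-class
#' @export
setMethod("eegData", "EEGRecording", function(x) x@data)

#' @rdname EEGRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname EEGRecording-class
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)

#' @rdname EEGRecording-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname EEGRecording-class
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@channels)

#' @rdname EEGRecording-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname EEGRecording-class
#' @export
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))

#' @rdname EEGRecording-class
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))
#' @rdname EEGRecording-class
#' @export
setMethod("duration", "EEGRecording", function(x) ncol(x@data) / x@fs)

#' @rdname LeadField-class
#' @param x a LeadField.
#' @export
setGeneric("leadfieldMatrix", function(x) standardGeneric("leadfieldMatrix"))
#' @rdname LeadField-class
#' @export
setMethod("leadfieldMatrix", "LeadField", function(x) x@L)

#' @rdname InverseOperator-class
#' @param x an InverseOperator.
#' @export
setGeneric("inverseMatrix", function(x) standardGeneric("inverseMatrix"))
#' @rdname InverseOperator-class
#' @export
setMethod("inverseMatrix", "InverseOperator", function(x) x@G)

#' @rdname FourierDesign-class
#' @param x a FourierDesign.
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))
#' @rdname FourierDesign-class
#' @export
setMethod("designMatrix", "FourierDesign", function(x) x@X0)

#' Frequency grid accessor
#' @param x an object carrying a frequency grid.
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))
#' @rdname frequencies
#' @export
setMethod("frequencies", "SensorTFR", function(x) x@freqs)
#' @rdname frequencies
#' @export
setMethod("frequencies", "SourceTFR", function(x) x@freqs)
#' @rdname frequencies
#' @export
setMethod("frequencies", "FourierDesign", function(x) x@freqs)
#' @rdname frequencies
#' @export
setMethod("frequencies", "FourierICAFit", function(x) x@freqs)

#' @rdname FourierICAFit-class
#' @param x a FourierICAFit.
#' @export
setGeneric("mixingMatrix", function(x) standardGeneric("mixingMatrix"))
#' @rdname FourierICAFit-class
#' @export
setMethod("mixingMatrix", "FourierICAFit", function(x) x@A)

#' @rdname FourierICAFit-class
#' @export
setGeneric("sourceMatrix", function(x) standardGeneric("sourceMatrix"))
#' @rdname FourierICAFit-class
#' @export
setMethod("sourceMatrix", "FourierICAFit", function(x) x@S)

#' @rdname FourierICAFit-class
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @rdname FourierICAFit-class
#' @export
setMethod("nComponents", "FourierICAFit", function(x) ncol(x@A))

#' @rdname FeatureSet-class
#' @param x a FeatureSet.
#' @export
setGeneric("featureSeries", function(x) standardGeneric("featureSeries"))
#' @rdname FeatureSet-class
#' @export
setMethod("featureSeries", "FeatureSet", function(x) x@series)

#' @rdname FeatureSet-class
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
#' @rdname FeatureSet-class
#' @export
setMethod("featureNames", "FeatureSet", function(x) rownames(x@series))

#' @rdname StabilityReport-class
#' @param x a StabilityReport.
#' @export
setGeneric("stabilityIndex", function(x) standardGeneric("stabilityIndex"))
#' @rdname StabilityReport-class
#' @export
setMethod("stabilityIndex", "StabilityReport", function(x) x@iq)

#' @rdname StabilityReport-class
#' @export
setGeneric("representativeFit", function(x) standardGeneric("representativeFit"))
#' @rdname StabilityReport-class
#' @export
setMethod("representativeFit", "StabilityReport", function(x) x@representative)

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording:", nrow(object@data), "channels x", ncol(object@data),
    "samples @", object@fs, "Hz (", format(ncol(object@data) / object@fs), "s )\n")
})

setMethod("show", "LeadField", function(object) {
  cat("LeadField:", nrow(object@L), "channels x", ncol(object@L), "sources\n")
})

setMethod("show", "InverseOperator", function(object) {
  cat("InverseOperator:", nrow(object@G), "sources x", ncol(object@G),
    "channels; lambda2 =", object@lambda2, "; depthGamma =", object@depthGamma, "\n")
})

setMethod("show", "SensorTFR", function(object) {
  d <- dim(object@coef)
  cat("SensorTFR:", d[1], "channels x", d[2], "freqs x", d[3], "times;",
    "band", min(object@freqs), "-", max(object@freqs), "Hz\n")
})

setMethod("show", "SourceTFR", function(object) {
  d <- dim(object@coef)
  cat("SourceTFR:", d[1], "sources x", d[2], "times x", d[3], "freqs\n")
})

setMethod("show", "FourierDesign", function(object) {
  cat("FourierDesign X0:", nrow(object@X0), "times x", ncol(object@X0),
    "(", length(object@freqs), "freqs x", object@nSources, "sources, source-major )\n")
})

setMethod("show", "FourierICAFit", function(object) {
  cat("FourierICAFit:", ncol(object@A), "components;",
    nrow(object@A), "time points;", ncol(object@S), "spatial-spectral columns;",
    if (object@converged) "converged" else "NOT converged",
    "in", object@nIter, "iterations\n")
})

setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet:", nrow(object@series), "features x", ncol(object@series),
    "samples @", object@rate, "Hz\n  ",
    paste(rownames(object@series), collapse = ", "), "\n")
})

setMethod("show", "StabilityReport", function(object) {
  cat("StabilityReport:", object@nRuns, "runs,", length(object@iq), "clusters; Iq range [",
    round(min(object@iq), 3), ",", round(max(object@iq), 3), "]\n")
})

setMethod("show", "CorrelationResult", function(object) {
  cat("CorrelationResult:", nrow(object@r), "components x", ncol(object@r),
    "features; |r| threshold", round(object@rCrit, 4), ";",
    nrow(object@retained), "pairs retained\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", object@M, "clusters over", length(object@assignment),
    "components from", length(unique(object@subjects)), "subjects;",
    sum(object@kept), "kept\n")
})

setMethod("show", "Scenario", function(object) {
  cat("Scenario:", object@nChannels, "channels,", object@nSources, "sources,",
    object@duration, "s @", object@fs, "Hz;", length(object@networks),
    "planted networks; seed", object@seed, "\n")
})

setMethod("show", "PlantedNetwork", function(object) {
  cat("PlantedNetwork:", object@carrierFreq, "Hz at source", object@centerSource,
    "(sd", object@spatialSd, ") driven by", object@featureName,
    "(coupling", object@coupling, ")\n")
})
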