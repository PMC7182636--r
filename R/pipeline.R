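# Orchestration: per-subject workflow (preprocess -> STFT -> inverse
# projection -> ICA/ICASSO -> characterize -> stimulus screening) and the
# group-level clustering, driven by one config list.

#' Default pipeline configuration
#'
#' All defaults follow the study design this workflow implements: 3-s Hamming
#' windows with 2-s overlap and a 512-point FFT on 256-Hz data, a 1-30 Hz
#' analysis band, model order 20 with 100 ICASSO runs and Iq threshold 0.7,
#' familywise alpha 0.05, and a half-of-subjects cluster retention rule.
#' Override any entry by name, or load overrides from YAML with
#' [readPipelineConfig()].
#'
#' @param ... named overrides of the nested defaults, e.g.
#'   `ica = list(order = 10)` (partial lists are merged).
#' @return nested configuration list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    preprocess = list(enabled = TRUE, notch = 50, hp = 1, lp = 30, fsOut = 256,
      dejump = TRUE, dejumpKernel = 9L),
    stft = list(frameS = 3, overlapS = 2, nfft = 512L, bandLo = 1, bandHi = 30),
    inverse = list(lambda2 = 0.1, depthGamma = 0.8),
    ica = list(order = 20L, runs = 100L, iqThresh = 0.7, maxIter = 1000L, tol = 1e-6),
    stats = list(alpha = 0.05, nSurrogates = 1000L, seed = 1L),
    cluster = list(Mmax = 10L, retainFrac = 0.5)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && nm %in% names(cfg)) {
      cfg[[nm]][names(ov[[nm]])] <- ov[[nm]]
    } else cfg[[nm]] <- ov[[nm]]
  }
  cfg
}

#' Load pipeline configuration overrides from YAML
#'
#' @param path YAML file whose top-level keys mirror [pipelineConfig()].
#' @return merged configuration list.
#' @export
readPipelineConfig <- function(path) {
  ov <- yaml::read_yaml(path)
  do.call(pipelineConfig, ov)
}

#' Run the per-subject workflow
#'
#' Common-average re-reference (plus the filter chain and DC-jump repair when
#' enabled), STFT, band selection, minimum-norm projection, design-matrix
#' unfolding, ICASSO (or a single FastICA fit when `runs = 1`), component
#' characterization, and stimulus-correlation screening. Every stage is
#' deterministic given the config seed; the subject index offsets the seed so
#' subjects are independent but reproducible.
#'
#' @param rec an [EEGRecording-class].
#' @param leadfield a [LeadField-class] matching the channel count.
#' @param features a [FeatureSet-class] at 1 Hz matching the duration.
#' @param config list from [pipelineConfig()].
#' @param subject integer subject id (default 1).
#' @param rCrit optional precomputed familywise threshold (shared across
#'   subjects when the features and family size are common).
#' @return list with `subject`, `report` ([StabilityReport-class] or `NULL`),
#'   `fit` ([FourierICAFit-class]), `summaries`, `screen`
#'   ([CorrelationResult-class]), and `retainedComponents` (data.frame of
#'   distinct retained components with their features).
#' @export
runSubject <- function(rec, leadfield, features, config = pipelineConfig(),
                       subject = 1L, rCrit = NULL) {
  seed <- as.integer(config$stats$seed) + 1009L * as.integer(subject)
  rec <- rereferenceCommonAverage(rec)
  if (isTRUE(config$preprocess$enabled)) {
    pp <- config$preprocess
    notch <- if (!is.null(pp$notch) && pp$notch < samplingRate(rec) / 2) pp$notch else NULL
    rec <- filterChain(rec, notch = notch, hp = pp$hp, lp = pp$lp,
      fsOut = min(pp$fsOut, samplingRate(rec)))
    if (isTRUE(pp$dejump)) rec <- removeDCJumpsRecording(rec, kernel = pp$dejumpKernel)
  }
  nfft <- config$stft$nfft
  if (is.null(nfft)) nfft <- as.integer(2 * samplingRate(rec))
  tfr <- stftEEG(rec, frameS = config$stft$frameS, overlapS = config$stft$overlapS,
    nfft = nfft)
  tfr <- selectBand(tfr, lo = config$stft$bandLo, hi = config$stft$bandHi)
  inv <- computeInverseOperator(leadfield, lambda2 = config$inverse$lambda2,
    depthGamma = config$inverse$depthGamma)
  design <- buildDesignMatrix(projectTFR(tfr, inv))
  report <- NULL
  if (config$ica$runs > 1L) {
    report <- runIcasso(design, order = config$ica$order, nRuns = config$ica$runs,
      seed = seed, maxIter = config$ica$maxIter, tol = config$ica$tol,
      iqThresh = config$ica$iqThresh)
    fit <- representativeFit(report)
  } else {
    fit <- fourierICA(design, order = config$ica$order, seed = seed,
      maxIter = config$ica$maxIter, tol = config$ica$tol)
  }
  summaries <- summarizeComponents(fit, subject = subject)
  screen <- selectStimComponents(fit, features, rCrit = rCrit,
    alpha = config$stats$alpha, nSurrogates = config$stats$nSurrogates,
    seed = as.integer(config$stats$seed))
  comps <- unique(screen@retained$component)
  retained <- data.frame(subject = rep(as.integer(subject), length(comps)),
    component = as.integer(comps))
  retained$features <- lapply(comps, function(k)
    screen@retained$feature[screen@retained$component == k])
  list(subject = as.integer(subject), report = report, fit = fit,
    summaries = summaries, screen = screen, retainedComponents = retained)
}

#' Pool subjects and cluster their retained components
#'
#' Collects the spatial power maps (and spectra) of every retained component
#' across subjects and delegates to [clusterGroup()]. With no retained
#' components an explicit empty result is returned rather than an error.
#'
#' @param subjectResults list of [runSubject()] results.
#' @param nSubjects total number of subjects in the study (defaults to the
#'   number of results).
#' @param config list from [pipelineConfig()].
#' @return A [ClusterResult-class], or `NULL` (with a message) when nothing
#'   was retained.
#' @export
runGroup <- function(subjectResults, nSubjects = length(subjectResults),
                     config = pipelineConfig()) {
  maps <- list(); subjects <- integer(0); featuresOf <- list(); spectra <- list()
  for (res in subjectResults) {
    rc <- res$retainedComponents
    for (i in seq_len(nrow(rc))) {
      k <- rc$component[i]
      maps[[length(maps) + 1L]] <- res$summaries[[k]]$power
      spectra[[length(spectra) + 1L]] <- res$summaries[[k]]$spectrum
      featuresOf[[length(featuresOf) + 1L]] <- rc$features[[i]]
      subjects <- c(subjects, rc$subject[i])
    }
  }
  if (length(maps) == 0L) {
    message("no components were retained; empty group result")
    return(NULL)
  }
  clusterGroup(do.call(rbind, maps), subjects = subjects, nSubjects = nSubjects,
    featuresOf = featuresOf, spectra = do.call(rbind, spectra),
    Mmax = config$cluster$Mmax)
}

#' Write a JSON summary of a group cluster result
#'
#' Persists membership, retention flags, subject counts and pairwise map
#' correlation statistics (not the full centroid maps) as provenance.
#'
#' @param result a [ClusterResult-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeClusterJSON <- function(result, path) {
  out <- list(M = result@M, assignment = result@assignment,
    kept = result@kept, subjects = result@subjects,
    clusters = lapply(result@summaries, function(s)
      list(subjectCount = s$subjectCount, meanCor = s$meanCor, sdCor = s$sdCor,
        perFeatureSubjects = as.list(s$perFeatureSubjects))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
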