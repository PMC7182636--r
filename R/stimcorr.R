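# Stimulus-correlation screening: Pearson correlation of component time
# courses with the 1-Hz feature series, thresholded by a Monte-Carlo
# max-statistic familywise criterion.

#' Pearson correlation with argument checks
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return correlation coefficient in [-1, 1].
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) < 3L) stop("need at least 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance input")
  stats::cor(x, y)
}

#' Monte-Carlo familywise correlation threshold
#'
#' Surrogate scheme: per draw, each feature series is circularly shifted by a
#' random offset of at least `minShift` samples (preserving its
#' autocorrelation) and correlated against fresh white-noise component
#' series; the maximum |r| over the whole comparison family is recorded, and
#' the threshold is the (1-alpha) quantile of that max-statistic
#' distribution — the familywise critical value. With no feature series
#' supplied, white-noise surrogate features are used, in which case the
#' single-comparison threshold approaches the Fisher approximation
#' `z_(1-alpha/2)/sqrt(n)`.
#'
#' @param n series length.
#' @param nComparisons size of the comparison family (components x features);
#'   must be a multiple of the feature count when `features` is given.
#' @param alpha familywise level in (0, 1) (default 0.05).
#' @param nSurrogates number of surrogate draws (default 1000; >= 1000
#'   recommended).
#' @param seed integer seed.
#' @param features optional [FeatureSet-class] or features x n matrix.
#' @param minShift minimum circular shift (default 10 samples).
#' @return critical |r| value.
#' @export
mcThreshold <- function(n, nComparisons, alpha = 0.05, nSurrogates = 1000L,
                        seed = 1L, features = NULL, minShift = 10L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (nComparisons < 1L) stop("need at least one comparison")
  fmat <- NULL
  if (!is.null(features)) {
    fmat <- if (is(features, "FeatureSet")) featureSeries(features) else as.matrix(features)
    if (ncol(fmat) != n) stop("feature length (", ncol(fmat), ") must equal n (", n, ")")
    if (nComparisons %% nrow(fmat) != 0L)
      stop("nComparisons must be a multiple of the feature count")
  }
  nFeat <- if (is.null(fmat)) 1L else nrow(fmat)
  k <- nComparisons %/% nFeat
  if (is.null(fmat)) k <- nComparisons
  set.seed(as.integer(seed))
  maxstat <- numeric(nSurrogates)
  for (b in seq_len(nSurrogates)) {
    comp <- matrix(stats::rnorm(n * k), n, k)
    if (is.null(fmat)) {
      feat <- matrix(stats::rnorm(n * nFeat), n, nFeat)
    } else {
      off <- sample(minShift:(n - minShift), nFeat, replace = TRUE)
      feat <- vapply(seq_len(nFeat), function(j) {
        x <- fmat[j, ]
        c(x[(off[j] + 1L):n], x[1:off[j]])
      }, numeric(n))
    }
    maxstat[b] <- max(abs(stats::cor(comp, feat)))
  }
  as.numeric(stats::quantile(maxstat, 1 - alpha))
}

#' Screen components against the stimulus features
#'
#' Computes all component-by-feature Pearson correlations and retains the
#' pairs whose |r| reaches the familywise threshold (two-sided on |r|).
#'
#' @param timecourses Nt x K matrix of component time courses, or a
#'   [FourierICAFit-class] (column moduli of the mixing matrix are used).
#' @param features a [FeatureSet-class] of matching length.
#' @param rCrit critical |r|; computed via [mcThreshold()] when `NULL`.
#' @param alpha,nSurrogates,seed passed to [mcThreshold()] when needed.
#' @return A [CorrelationResult-class].
#' @export
selectStimComponents <- function(timecourses, features, rCrit = NULL,
                                 alpha = 0.05, nSurrogates = 1000L, seed = 1L) {
  if (is(timecourses, "FourierICAFit")) timecourses <- Mod(mixingMatrix(timecourses))
  tc <- as.matrix(timecourses)
  fmat <- featureSeries(features)
  if (nrow(tc) != ncol(fmat))
    stop("time course length (", nrow(tc), ") must equal feature length (", ncol(fmat), ")")
  if (is.null(rCrit))
    rCrit <- mcThreshold(n = nrow(tc), nComparisons = ncol(tc) * nrow(fmat),
      alpha = alpha, nSurrogates = nSurrogates, seed = seed, features = features)
  r <- stats::cor(tc, t(fmat))
  colnames(r) <- rownames(fmat)
  hits <- which(abs(r) >= rCrit, arr.ind = TRUE)
  retained <- data.frame(component = as.integer(hits[, 1]),
    feature = rownames(fmat)[hits[, 2]],
    r = r[hits], stringsAsFactors = FALSE)
  retained <- retained[order(retained$component, retained$feature), , drop = FALSE]
  rownames(retained) <- NULL
  new("CorrelationResult", r = r, rCrit = as.numeric(rCrit), retained = retained,
    alpha = as.numeric(alpha), nSurrogates = as.integer(nSurrogates),
    seed = as.integer(seed))
}
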