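# Group-level clustering of retained components' spatial maps: z-scoring,
# k-means with deterministic Kaufman seeding, MDL model-order selection, the
# majority-subject retention rule, and per-cluster summaries.

#' Z-score spatial maps
#'
#' Each row (one component's spatial map) is normalized to mean 0, SD 1.
#' Constant maps cannot be normalized and raise an error naming the row.
#'
#' @param maps components x Ns numeric matrix.
#' @return matrix of the same shape.
#' @export
zscoreMaps <- function(maps) {
  maps <- as.matrix(maps)
  sds <- apply(maps, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant spatial map(s) cannot be z-scored: row ",
      paste(which(sds == 0), collapse = ", "))
  t(scale(t(maps)))[, , drop = FALSE]
}

# Kaufman seeding: first seed is the most central point; each further seed
# maximizes the total coverage gain over still-unselected points
kaufmanSeeds <- function(D, M) {
  n <- nrow(D)
  sel <- which.min(colSums(D))
  while (length(sel) < M) {
    cand <- setdiff(seq_len(n), sel)
    cand <- cand[apply(D[cand, sel, drop = FALSE], 1L, min) > 0]  # skip duplicates
    if (length(cand) == 0L) stop("fewer than M distinct points")
    dNear <- apply(D[, sel, drop = FALSE], 1L, min)
    gains <- vapply(cand, function(i) {
      others <- setdiff(cand, i)
      if (length(others) == 0L) return(0)
      sum(pmax(dNear[others] - D[i, others], 0))
    }, numeric(1))
    sel <- c(sel, cand[which.max(gains)])
  }
  sel
}

#' k-means with deterministic Kaufman initialization
#'
#' The Kaufman Approach picks the most central point as the first seed and
#' then greedily adds the point with the largest coverage gain, so the
#' initialization (and hence the whole fit) is deterministic. Lloyd
#' iterations then run to convergence.
#'
#' @param maps components x d numeric matrix.
#' @param M number of clusters (1 <= M <= rows).
#' @param maxIter Lloyd iteration cap (default 100).
#' @return list with `assignment`, `centroids` (M x d), `withinss` (total
#'   within-cluster sum of squares), `seeds` (row indices used as initial
#'   centers).
#' @export
kmeansKA <- function(maps, M, maxIter = 100L) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (M < 1) stop("M must be >= 1")
  if (M > n) stop("M exceeds the number of maps")
  if (M == 1) {
    ctr <- matrix(colMeans(maps), 1)
    return(list(assignment = rep(1L, n), centroids = ctr,
      withinss = sum(sweep(maps, 2, ctr)^2), seeds = 1L))
  }
  D <- as.matrix(stats::dist(maps))
  seeds <- kaufmanSeeds(D, M)
  km <- suppressWarnings(stats::kmeans(maps, centers = maps[seeds, , drop = FALSE],
    iter.max = maxIter, algorithm = "Lloyd"))
  list(assignment = as.integer(km$cluster), centroids = km$centers,
    withinss = sum(km$withinss), seeds = seeds)
}

#' MDL selection of the cluster count
#'
#' Evaluates the k-means distortion at each order m = 1..Mmax on the maps
#' projected to their top principal subspace (effective dimension
#' `d = min(N-1, 50, ncol)`, keeping the penalty term non-degenerate for
#' high-dimensional maps) and minimizes the two-part code length
#' `(N*d/2)*log(RSS_m/(N*d)) + penalty*m*d*log(N*d)`: a spherical-Gaussian
#' coding cost for the N*d scalar observations plus log(N*d)/2 per centroid
#' parameter.
#'
#' The search stops at `floor(N/2)` clusters: beyond that the distortion can
#' reach zero (centroids become copies of single maps) and the code length
#' degenerates.
#'
#' @param maps components x Ns matrix (z-scored).
#' @param Mmax largest order considered (>= 2).
#' @param penalty per-parameter penalty weight (default 0.5).
#' @return selected integer order M.
#' @export
mdlOrder <- function(maps, Mmax, penalty = 0.5) {
  maps <- as.matrix(maps)
  N <- nrow(maps)
  if (N < 2L) stop("need at least 2 maps")
  if (Mmax < 2L) stop("Mmax must be >= 2")
  d <- min(N - 1L, 50L, ncol(maps))
  proj <- if (ncol(maps) > d) stats::prcomp(maps, center = TRUE, rank. = d)$x else maps
  dEff <- ncol(proj)
  Ms <- seq_len(max(1L, min(Mmax, N %/% 2L)))
  cost <- vapply(Ms, function(m) {
    rss <- tryCatch(kmeansKA(proj, m)$withinss, error = function(e) NA_real_)
    if (is.na(rss)) return(Inf)
    (N * dEff / 2) * log(max(rss, 1e-12) / (N * dEff)) +
      penalty * m * dEff * log(N * dEff)
  }, numeric(1))
  Ms[which.min(cost)]
}

#' Majority-subject retention rule
#'
#' A cluster is kept only when it spans at least `ceil(nSubjects/2)` distinct
#' subjects — fewer would not reveal structure shared among enough
#' participants.
#'
#' @param assignment cluster id per component.
#' @param subjects subject id per component.
#' @param nSubjects total number of subjects in the study.
#' @return named logical vector, one flag per cluster id.
#' @export
retainClusters <- function(assignment, subjects, nSubjects) {
  ids <- sort(unique(assignment))
  need <- ceiling(nSubjects / 2)
  out <- vapply(ids, function(i)
    length(unique(subjects[assignment == i])) >= need, logical(1))
  names(out) <- ids
  out
}

#' Summarize one cluster of spatial maps
#'
#' @param maps member maps (members x Ns, z-scored).
#' @param subjects subject id per member.
#' @param featuresOf list of character vectors: the features each member's
#'   time course was correlated with.
#' @param spectra optional members x Nf matrix of member spectra.
#' @return list with `centroid`, `meanCor`/`sdCor` (pairwise map
#'   correlations; NA and `undefined = TRUE` for a singleton),
#'   `subjectCount`, `perFeatureSubjects` (distinct subjects per feature),
#'   `spectra`.
#' @export
summarizeCluster <- function(maps, subjects, featuresOf = NULL, spectra = NULL) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  centroid <- colMeans(maps)
  if (n >= 2L) {
    cc <- stats::cor(t(maps))
    pair <- cc[upper.tri(cc)]
    meanCor <- mean(pair); sdCor <- stats::sd(pair); undefined <- FALSE
    if (n == 2L) sdCor <- 0
  } else {
    meanCor <- NA_real_; sdCor <- NA_real_; undefined <- TRUE
  }
  perFeature <- integer(0)
  if (!is.null(featuresOf)) {
    feats <- unique(unlist(featuresOf))
    perFeature <- vapply(feats, function(f)
      length(unique(subjects[vapply(featuresOf, function(v) f %in% v, logical(1))])),
      integer(1))
    names(perFeature) <- feats
  }
  list(centroid = centroid, meanCor = meanCor, sdCor = sdCor,
    undefined = undefined, subjectCount = length(unique(subjects)),
    perFeatureSubjects = perFeature, spectra = spectra)
}

#' Group-level clustering of retained component maps
#'
#' Z-scores the pooled spatial maps, selects the cluster count by
#' [mdlOrder()] (unless `M` is forced), partitions with [kmeansKA()], applies
#' the majority-subject retention rule and summarizes every cluster.
#'
#' @param maps pooled components x Ns matrix of spatial power maps.
#' @param subjects subject id per component.
#' @param nSubjects total subjects in the study.
#' @param featuresOf optional list (per component) of associated feature
#'   names.
#' @param spectra optional components x Nf matrix of component spectra.
#' @param Mmax MDL search limit (default 10).
#' @param M optional forced cluster count (skips MDL).
#' @return A [ClusterResult-class].
#' @export
clusterGroup <- function(maps, subjects, nSubjects, featuresOf = NULL,
                         spectra = NULL, Mmax = 10L, M = NULL) {
  z <- zscoreMaps(maps)
  if (is.null(M)) M <- mdlOrder(z, Mmax = Mmax)
  km <- kmeansKA(z, M)
  kept <- retainClusters(km$assignment, subjects, nSubjects)
  summaries <- lapply(sort(unique(km$assignment)), function(i) {
    m <- which(km$assignment == i)
    summarizeCluster(z[m, , drop = FALSE], subjects[m],
      featuresOf = if (is.null(featuresOf)) NULL else featuresOf[m],
      spectra = if (is.null(spectra)) NULL else spectra[m, , drop = FALSE])
  })
  new("ClusterResult", M = as.integer(M), assignment = as.integer(km$assignment),
    centroids = km$centroids, kept = as.logical(kept), summaries = summaries,
    subjects = as.integer(subjects))
}
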