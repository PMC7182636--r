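# Complex-valued ICASSO: repeated FastICA under random initial conditions,
# average-linkage clustering of pooled components on magnitude correlation,
# and the Iq cluster-quality (stability) index.

#' Magnitude-correlation similarity of complex components
#'
#' Entries are the absolute Pearson correlations between the magnitude
#' vectors of the component rows — invariant to the unit-modulus phase
#' indeterminacy of complex ICA. Zero-variance magnitude vectors get zero
#' rows/columns (with a warning); the diagonal is 1.
#'
#' @param components complex matrix, one component per row (equal lengths).
#' @return symmetric matrix in [0, 1] with unit diagonal.
#' @export
similarityMatrix <- function(components) {
  if (nrow(components) < 2L) stop("need at least 2 components")
  mags <- Mod(components)
  sds <- apply(mags, 1L, stats::sd)
  bad <- which(sds == 0)
  if (length(bad)) {
    warning("zero-variance magnitude vector(s): ", paste(bad, collapse = ", "))
    mags[bad, ] <- stats::rnorm(ncol(mags) * length(bad))  # placeholder, zeroed below
  }
  sim <- abs(stats::cor(t(mags)))
  if (length(bad)) { sim[bad, ] <- 0; sim[, bad] <- 0 }
  diag(sim) <- 1
  sim
}

#' Average-linkage partition of pooled components
#'
#' Agglomerative clustering on the dissimilarity `1 - similarity` with
#' average linkage (the ICASSO default), cut at `k` clusters.
#'
#' @param similarity symmetric similarity matrix in [0, 1].
#' @param k number of clusters (typically the ICA model order).
#' @return integer cluster id per component.
#' @export
clusterComponents <- function(similarity, k) {
  n <- nrow(similarity)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of components")
  hc <- stats::hclust(stats::as.dist(1 - similarity), method = "average")
  stats::cutree(hc, k = k)
}

#' Iq stability index per cluster
#'
#' `Iq_i` is the mean intra-cluster similarity (over off-diagonal member
#' pairs; 1 for a singleton) minus the mean similarity between cluster `i`
#' members and all non-members. A tight, isolated cluster — a component
#' re-estimated in almost every run — scores near 1.
#'
#' @param similarity symmetric similarity matrix.
#' @param partition integer cluster ids covering all components.
#' @return numeric vector, one Iq per cluster id (sorted by id).
#' @export
iqIndex <- function(similarity, partition) {
  ids <- sort(unique(partition))
  vapply(ids, function(i) {
    m <- which(partition == i)
    o <- which(partition != i)
    intra <- if (length(m) < 2L) 1 else {
      sub <- similarity[m, m]
      mean(sub[upper.tri(sub)])
    }
    ext <- if (length(o) == 0L) 0 else mean(similarity[m, o, drop = FALSE])
    intra - ext
  }, numeric(1))
}

#' ICASSO stability analysis of the Fourier-ICA decomposition
#'
#' Whitens once, then runs [complexFastICA()] `nRuns` times with distinct
#' derived seeds, pools all `order * nRuns` components, clusters them on
#' magnitude correlation into `order` clusters, and computes Iq per cluster.
#' Runs that fail to converge are recorded, excluded and warned about. The
#' representative decomposition is assembled from the centrotypes (each
#' cluster's member with maximal average intra-cluster similarity); clusters
#' are ordered by decreasing Iq.
#'
#' @param design a [FourierDesign-class].
#' @param order ICA model order (default 20).
#' @param nRuns number of randomly initialized runs (default 100).
#' @param seed base seed; run r uses `seed + r`.
#' @param maxIter,tol FastICA iteration settings.
#' @param iqThresh stability threshold used by [stableComponents()]
#'   (default 0.7).
#' @param runSeeds optional explicit seed per run, overriding the `seed + r`
#'   derivation (length defines `nRuns`).
#' @return A [StabilityReport-class].
#' @export
runIcasso <- function(design, order = 20L, nRuns = 100L, seed = 1L,
                      maxIter = 1000L, tol = 1e-6, iqThresh = 0.7,
                      runSeeds = NULL) {
  if (is.null(runSeeds)) runSeeds <- as.integer(seed) + seq_len(nRuns)
  nRuns <- length(runSeeds)
  pca <- complexPCA(design, order = order)
  fits <- vector("list", nRuns)
  ok <- logical(nRuns)
  for (r in seq_len(nRuns)) {
    fit <- complexFastICA(pca$Z, seed = runSeeds[r], maxIter = maxIter, tol = tol)
    fits[[r]] <- fit
    ok[r] <- fit$converged
  }
  if (!any(ok)) stop("no FastICA run converged")
  if (any(!ok))
    warning(sum(!ok), " of ", nRuns, " runs did not converge and were excluded")
  used <- which(ok)
  pooledS <- do.call(rbind, lapply(used, function(r) fits[[r]]$W %*% pca$Z))
  pooledA <- do.call(cbind, lapply(used, function(r) pca$dewhitener %*% Conj(t(fits[[r]]$W))))
  sim <- similarityMatrix(pooledS)
  part <- clusterComponents(sim, k = order)
  iq <- iqIndex(sim, part)
  ids <- sort(unique(part))
  ord <- order(iq, decreasing = TRUE)
  centro <- vapply(ids[ord], function(i) {
    m <- which(part == i)
    if (length(m) == 1L) return(m)
    m[which.max(rowMeans(sim[m, m, drop = FALSE]))]
  }, integer(1))
  # relabel clusters 1..order by decreasing Iq
  relabel <- integer(length(ids)); relabel[ord] <- seq_along(ids)
  partOut <- relabel[match(part, ids)]
  rep <- new("FourierICAFit",
    A = pooledA[, centro, drop = FALSE], S = pooledS[centro, , drop = FALSE],
    whitener = pca$whitener, dewhitener = pca$dewhitener,
    rowMeans = pca$rowMeans, eigvals = pca$eigvals,
    freqs = design@freqs, nSources = design@nSources,
    nIter = as.integer(max(vapply(fits[used], `[[`, integer(1) + 0L, "nIter"))),
    converged = TRUE, seed = as.integer(seed))
  structure(new("StabilityReport", nRuns = length(used), similarity = sim,
    partition = as.integer(partOut), iq = iq[ord], centrotypes = centro,
    representative = rep), iqThresh = iqThresh)
}

#' Which clusters pass the stability threshold?
#'
#' @param report a [StabilityReport-class].
#' @param thresh Iq threshold (default 0.7).
#' @return logical vector per cluster (decomposition considered stable where
#'   Iq exceeds the threshold).
#' @export
stableComponents <- function(report, thresh = 0.7) {
  stabilityIndex(report) > thresh
}
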