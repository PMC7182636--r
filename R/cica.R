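# Complex-valued PCA whitening and complex FastICA (Bingham-Hyvarinen fixed
# point with symmetric decorrelation) on the unfolded Fourier design matrix.

asDesignMatrix <- function(X0) {
  if (is(X0, "FourierDesign")) designMatrix(X0) else as.matrix(X0)
}

#' Complex-valued PCA whitening
#'
#' Rows of X0 are mean-centered; the Hermitian covariance `Xc Xc^H / m` is
#' eigendecomposed; the top `order` eigenpairs form the whitening pair. The
#' whitened matrix Z has (Hermitian) identity covariance, and
#' `dewhitener %*% Z` reconstructs the rank-`order` part of the centered X0.
#'
#' @param X0 a [FourierDesign-class] or complex matrix (rows = time windows).
#' @param order retained dimension (default 20); must not exceed the
#'   numerical rank of the centered matrix.
#' @return list with `Z` (order x m), `whitener` (order x Nt), `dewhitener`
#'   (Nt x order), `eigvals` (all eigenvalues, real, descending) and
#'   `rowMeans` (the removed complex row means).
#' @export
complexPCA <- function(X0, order = 20L) {
  X <- asDesignMatrix(X0)
  if (!is.complex(X)) X <- X + 0i
  m <- ncol(X)
  if (order > nrow(X)) stop("order exceeds the number of rows")
  rm <- rowMeans(X)
  Xc <- X - rm
  C <- (Xc %*% Conj(t(Xc))) / m
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  tol <- max(vals) * 1e-10
  rank <- sum(vals > tol)
  if (order > rank)
    stop("order (", order, ") exceeds the numerical rank (", rank, ") of the data")
  idx <- seq_len(order)
  scale <- 1 / sqrt(vals[idx])
  whitener <- scale * Conj(t(e$vectors[, idx, drop = FALSE]))
  dewhitener <- e$vectors[, idx, drop = FALSE] *
    rep(sqrt(vals[idx]), each = nrow(X))
  list(Z = whitener %*% Xc, whitener = whitener, dewhitener = dewhitener,
    eigvals = vals, rowMeans = rm)
}

symDecorrelate <- function(W) {
  M <- W %*% Conj(t(W))
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% ((1 / sqrt(pmax(e$values, .Machine$double.eps))) *
    Conj(t(e$vectors))) %*% W
}

#' Complex FastICA on whitened data
#'
#' Parallel (symmetric-decorrelation) fixed-point iteration with the robust
#' contrast `G(u) = sqrt(eps + u)` applied to `u = |w^H z|^2`. Each update is
#' `w <- E{z (w^H z)* g(u)} - E{g(u) + u g'(u)} w` followed by symmetric
#' decorrelation `W <- (W W^H)^(-1/2) W`, so the returned unmixing matrix is
#' unitary. Convergence is declared when
#' `1 - min diag |W_new W_old^H| < tol`.
#'
#' @param Z whitened complex matrix (order x m), e.g. from [complexPCA()];
#'   inputs whose covariance deviates from identity by more than 1e-3 are
#'   rejected.
#' @param seed integer seed for the random unitary initialization.
#' @param maxIter iteration cap (default 1000).
#' @param tol convergence tolerance (default 1e-6).
#' @param eps contrast smoothing constant (default 0.1).
#' @return list with `W` (unitary order x order), `nIter`, `converged`.
#' @export
complexFastICA <- function(Z, seed = 1L, maxIter = 1000L, tol = 1e-6, eps = 0.1) {
  n <- nrow(Z)
  m <- ncol(Z)
  dev <- max(abs(Z %*% Conj(t(Z)) / m - diag(n)))
  if (dev > 1e-3)
    stop("input is not whitened (covariance deviates from identity by ", signif(dev, 3), ")")
  set.seed(as.integer(seed))
  W <- matrix(complex(real = stats::rnorm(n * n), imaginary = stats::rnorm(n * n)), n, n)
  W <- symDecorrelate(W)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    U <- W %*% Z                                  # rows u_k = w_k^H z
    u2 <- Re(U * Conj(U))
    g <- 1 / (2 * sqrt(eps + u2))
    gp <- -1 / (4 * (eps + u2)^1.5)
    B <- Z %*% t(Conj(U) * g) / m                 # col k = E{z conj(u_k) g_k}
    cvec <- rowMeans(g + u2 * gp)
    V <- Conj(t(W))                               # col k = w_k
    Vnew <- B - V %*% diag(cvec, n)
    Wnew <- symDecorrelate(Conj(t(Vnew)))
    delta <- 1 - min(abs(diag(Wnew %*% Conj(t(W)))))
    W <- Wnew
    if (delta < tol) { converged <- TRUE; break }
  }
  list(W = W, nIter = it, converged = converged)
}

#' Assemble the Fourier-ICA decomposition
#'
#' Combines the whitening pair and the unitary unmixing matrix into the final
#' factorization of the centered design matrix: `S = W Z` (rows are unit
#' variance spatial-spectral patterns) and `A = dewhitener W^H`, so
#' `A %*% S` equals the rank-`order` PCA reconstruction.
#'
#' @param design the [FourierDesign-class] that was decomposed.
#' @param pca the list returned by [complexPCA()].
#' @param ica the list returned by [complexFastICA()].
#' @param seed the seed recorded in the fit.
#' @return A [FourierICAFit-class].
#' @export
unmix <- function(design, pca, ica, seed = 1L) {
  S <- ica$W %*% pca$Z
  A <- pca$dewhitener %*% Conj(t(ica$W))
  new("FourierICAFit", A = A, S = S, whitener = pca$whitener,
    dewhitener = pca$dewhitener, rowMeans = pca$rowMeans, eigvals = pca$eigvals,
    freqs = design@freqs, nSources = design@nSources,
    nIter = as.integer(ica$nIter), converged = ica$converged,
    seed = as.integer(seed))
}

#' One-call spatial Fourier-ICA
#'
#' [complexPCA()] + [complexFastICA()] + [unmix()] with a single seed.
#'
#' @inheritParams complexPCA
#' @inheritParams complexFastICA
#' @param design a [FourierDesign-class].
#' @return A [FourierICAFit-class].
#' @export
fourierICA <- function(design, order = 20L, seed = 1L, maxIter = 1000L, tol = 1e-6) {
  pca <- complexPCA(design, order = order)
  ica <- complexFastICA(pca$Z, seed = seed, maxIter = maxIter, tol = tol)
  if (!ica$converged)
    warning("FastICA did not converge in ", maxIter, " iterations")
  unmix(design, pca, ica, seed = seed)
}
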