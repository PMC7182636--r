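test_that("complex PCA whitens to identity covariance", {
  X <- complexMatrix(6, 400, seed = 1)
  pca <- complexPCA(X, order = 6)
  dev <- max(abs(pca$Z %*% Conj(t(pca$Z)) / ncol(X) - diag(6)))
  expect_lt(dev, 1e-8)
})

test_that("a rank-3 matrix is reconstructed exactly at order 3", {
  A <- complexMatrix(8, 3, seed = 2)
  S <- complexMatrix(3, 200, seed = 3)
  X <- A %*% S
  pca <- complexPCA(X, order = 3)
  rec <- pca$dewhitener %*% pca$Z + pca$rowMeans
  expect_lt(max(Mod(rec - X)) / max(Mod(X)), 1e-8)
})

test_that("eigenvalues match an independent SVD oracle", {
  X <- complexMatrix(6, 40, seed = 4)
  pca <- complexPCA(X, order = 6)
  Xc <- X - rowMeans(X)
  sv <- svd(Xc)$d
  expect_equal(pca$eigvals, sv^2 / 40, tolerance = 1e-10)
})

test_that("requesting more components than the rank reports the rank", {
  A <- complexMatrix(8, 3, seed = 5)
  S <- complexMatrix(3, 100, seed = 6)
  expect_error(complexPCA(A %*% S, order = 5), "rank \\(3\\)")
})

test_that("FastICA requires whitened input and returns a unitary matrix", {
  X <- complexMatrix(4, 500, seed = 7)
  expect_error(complexFastICA(3 * X, seed = 1), "not whitened")

  pca <- complexPCA(X, order = 4)
  ica <- complexFastICA(pca$Z, seed = 1)
  expect_lt(max(abs(ica$W %*% Conj(t(ica$W)) - diag(4))), 1e-8)
})

test_that("FastICA unmixes a random unitary mixture of non-Gaussian complex sources", {
  set.seed(42)
  m <- 20000; n <- 3
  S <- matrix(rexp(n * m), n, m) * exp(1i * matrix(runif(n * m, 0, 2 * pi), n, m))
  Q <- qr.Q(qr(complexMatrix(n, n, seed = 9)))
  X <- Q %*% S
  pca <- complexPCA(X, order = n)
  ica <- complexFastICA(pca$Z, seed = 1)
  expect_true(ica$converged)
  Sh <- ica$W %*% pca$Z
  cc <- abs(cor(t(Mod(Sh)), t(Mod(S))))
  matched <- apply(cc, 2, max)
  expect_true(all(matched > 0.95))
})

test_that("FastICA is seed-deterministic and seed-invariant up to permutation/phase", {
  set.seed(43)
  m <- 20000
  S <- matrix(rexp(3 * m), 3, m) * exp(1i * matrix(runif(3 * m, 0, 2 * pi), 3, m))
  pca <- complexPCA(qr.Q(qr(complexMatrix(3, 3, seed = 10))) %*% S, order = 3)
  a <- complexFastICA(pca$Z, seed = 5)
  b <- complexFastICA(pca$Z, seed = 5)
  expect_identical(a$W, b$W)
  c <- complexFastICA(pca$Z, seed = 6)
  cc <- abs(cor(t(Mod(a$W %*% pca$Z)), t(Mod(c$W %*% pca$Z))))
  expect_true(all(apply(cc, 2, max) > 0.999))
})

test_that("the decomposition reconstructs the centered design to the PCA residual", {
  des <- smallSubject()$design
  fit <- smallFit()
  X <- designMatrix(des)
  Xc <- X - rowMeans(X)
  resid <- sum(Mod(Xc - mixingMatrix(fit) %*% sourceMatrix(fit))^2) / sum(Mod(Xc)^2)
  ev <- fit@eigvals
  tail <- 1 - sum(ev[1:6]) / sum(ev)
  expect_equal(resid, tail, tolerance = 1e-6)
  # rows of S carry unit variance under the ICA scaling convention
  expect_equal(rowMeans(Mod(sourceMatrix(fit))^2), rep(1, 6), tolerance = 1e-8)
})

test_that("full-order decomposition of a low-rank toy is exact and scales linearly", {
  A <- complexMatrix(6, 2, seed = 11)
  S <- matrix(rexp(2 * 5000), 2, 5000) *
    exp(1i * matrix(runif(2 * 5000, 0, 2 * pi), 2, 5000))
  X <- A %*% S
  des <- new("FourierDesign", X0 = X, freqs = c(1), nSources = 5000L,
    times = seq_len(6) - 0.5)
  fit <- fourierICA(des, order = 2, seed = 1)
  Xc <- X - rowMeans(X)
  expect_lt(max(Mod(Xc - mixingMatrix(fit) %*% sourceMatrix(fit))), 1e-6)

  fit2 <- fourierICA(new("FourierDesign", X0 = (2 + 1i) * X, freqs = c(1),
    nSources = 5000L, times = seq_len(6) - 0.5), order = 2, seed = 1)
  expect_equal(mixingMatrix(fit2) %*% sourceMatrix(fit2),
    (2 + 1i) * (mixingMatrix(fit) %*% sourceMatrix(fit)), tolerance = 1e-6)
})

test_that("a planted network concentrates one component's energy on its support", {
  sub <- smallSubject()
  fit <- smallFit()
  nf <- length(frequencies(fit))
  freqs <- frequencies(fit)
  for (k in seq_along(sub$sim$truth)) {
    tr <- sub$sim$truth[[k]]
    srcIdx <- which(tr$weights > 0.05)
    frIdx <- which(abs(freqs - tr$carrier) <= 0.75)
    fracs <- vapply(seq_len(nComponents(fit)), function(i)
      supportEnergyFraction(sourceMatrix(fit)[i, ], nf, 100L, srcIdx, frIdx),
      numeric(1))
    expect_gte(max(fracs), 0.5)
  }
})
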