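test_that("magnitude-correlation similarity is phase-invariant with unit diagonal", {
  X <- complexMatrix(4, 200, seed = 1)
  sim <- similarityMatrix(X)
  expect_equal(diag(sim), rep(1, 4))
  expect_equal(sim, t(sim))

  pair <- rbind(X[1, ], X[1, ] * exp(1i * 0.7))
  expect_equal(similarityMatrix(pair)[1, 2], 1, tolerance = 1e-12)

  indep <- complexMatrix(2, 1e4, seed = 2)
  expect_lt(similarityMatrix(indep)[1, 2], 0.05)

  Z <- X
  Z[2, ] <- 3 + 0i  # constant magnitude
  expect_warning(s2 <- similarityMatrix(Z), "zero-variance")
  expect_true(all(s2[2, -2] == 0))
})

test_that("average-linkage clustering separates copied prototypes and matches a brute-force oracle", {
  set.seed(3)
  protos <- diag(3)[, c(1, 2, 3)]
  comps <- complexMatrix(3, 120, seed = 4)  # 3 orthogonal-ish prototypes
  # 100 noisy copies of each prototype row
  pool <- do.call(rbind, lapply(rep(1:3, each = 100), function(i)
    comps[i, ] * exp(1i * runif(1, 0, 2 * pi))))
  sim <- similarityMatrix(pool)
  part <- clusterComponents(sim, 3)
  expect_equal(length(unique(part)), 3L)
  truth <- rep(1:3, each = 100)
  expect_true(all(table(part, truth) %in% c(0L, 100L)))

  # brute-force average linkage on 6 components
  X <- complexMatrix(6, 30, seed = 5)
  s6 <- similarityMatrix(X)
  d <- 1 - s6
  groups <- as.list(1:6)
  while (length(groups) > 3) {
    best <- c(Inf, 0, 0)
    for (a in seq_along(groups)) for (b in seq_along(groups)) if (a < b) {
      avg <- mean(d[groups[[a]], groups[[b]]])
      if (avg < best[1]) best <- c(avg, a, b)
    }
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups <- groups[-best[3]]
  }
  oracle <- integer(6)
  for (g in seq_along(groups)) oracle[groups[[g]]] <- g
  part6 <- clusterComponents(s6, 3)
  # same partition up to label permutation
  expect_equal(length(unique(paste(part6, oracle))), 3L)

  expect_identical(unname(clusterComponents(s6, 6)), 1:6)
  expect_error(clusterComponents(s6, 0), ">= 1")
})

test_that("the Iq index follows its defining arithmetic", {
  # two clusters of duplicated orthogonal components: intra 1, inter 0
  sim <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(iqIndex(sim, c(1, 1, 2, 2)), c(1, 1))

  # one tight pair plus unrelated noise components
  sim2 <- diag(4); sim2[1, 2] <- sim2[2, 1] <- 1
  sim2[sim2 == 0] <- 0.02
  iq <- iqIndex(sim2, c(1, 1, 2, 3))
  expect_equal(iq[1], 1 - 0.02, tolerance = 1e-12)

  # all components identical: intra 1, inter 1 -> Iq 0
  ones <- matrix(1, 4, 4)
  expect_equal(iqIndex(ones, c(1, 1, 2, 2)), c(0, 0))

  # singleton intra-similarity defined as 1
  expect_equal(iqIndex(diag(3), c(1, 2, 3)), c(1, 1, 1))
})

test_that("Iq is invariant to phase rotation and run permutation of the pool", {
  X <- complexMatrix(6, 300, seed = 6)
  sim <- similarityMatrix(X)
  part <- clusterComponents(sim, 3)
  iq <- iqIndex(sim, part)

  set.seed(7)
  Xr <- X * exp(1i * runif(6, 0, 2 * pi))
  perm <- sample(6)
  simP <- similarityMatrix(Xr[perm, ])
  expect_equal(sort(iqIndex(simP, part[perm])), sort(iq), tolerance = 1e-10)
})

test_that("identical-seed runs give Iq = 1 for every cluster, up to residual inter-cluster correlation", {
  # with identical runs every cluster is a pair of exact duplicates: the
  # intra-cluster similarity is exactly 1, so Iq = 1 minus the (near-zero for
  # independent sources) inter-cluster magnitude correlation
  set.seed(12)
  m <- 20000
  S <- matrix(rexp(4 * m), 4, m) * exp(1i * matrix(runif(4 * m, 0, 2 * pi), 4, m))
  des <- new("FourierDesign", X0 = complexMatrix(8, 4, seed = 13) %*% S,
    freqs = c(1, 2), nSources = as.integer(m / 2), times = seq_len(8) - 0.5)
  rep2 <- runIcasso(des, order = 4, runSeeds = c(5L, 5L))
  # duplicates pair up: every cluster has one member from each run
  expect_true(all(table(rep2@partition) == 2))
  for (i in 1:4) {
    mem <- which(rep2@partition == i)
    expect_equal(rep2@similarity[mem[1], mem[2]], 1, tolerance = 1e-10)
  }
  expect_equal(stabilityIndex(rep2), rep(1, 4), tolerance = 0.05)
})

test_that("ICASSO on a high-SNR planted subject is stable and bounded", {
  des <- smallSubject()$design
  rep <- runIcasso(des, order = 6, nRuns = 8, seed = 21)
  iq <- stabilityIndex(rep)
  expect_true(all(iq >= 0 & iq <= 1))
  expect_true(all(iq > 0.9))
  expect_equal(rep@nRuns, 8L)
  expect_true(all(stableComponents(rep)))
  # representative decomposition has the requested order
  expect_equal(nComponents(representativeFit(rep)), 6L)
})

test_that("adding unrelated noise components cannot decrease a tight cluster's Iq", {
  X <- complexMatrix(2, 5000, seed = 8)
  tight <- rbind(X[1, ], X[1, ] * exp(1i * 1.1))
  base <- similarityMatrix(rbind(tight, X[2, ]))
  iqBase <- iqIndex(base, c(1, 1, 2))[1]
  more <- similarityMatrix(rbind(tight, X[2, ], complexMatrix(2, 5000, seed = 9)))
  iqMore <- iqIndex(more, c(1, 1, 2, 3, 4))[1]
  expect_gte(iqMore, iqBase - 0.02)
})
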