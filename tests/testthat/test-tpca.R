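test_that("objective evaluates its three terms exactly", {
  # 2x2 identity, U = Q = first standard basis column, beta = 1:
  # reconstruction L2,1 = 1, sparsity = 1, total 2
  X <- diag(2)
  u <- matrix(c(1, 0), 2, 1)
  q <- matrix(c(1, 0), 2, 1)
  expect_equal(tpcaObjective(X, u, q, NULL, beta = 1, gamma = 0), 2)

  # perfect reconstruction with a full orthonormal Q
  set.seed(1)
  X2 <- matrix(rnorm(12), 3, 4)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_lt(tpcaObjective(X2, X2 %*% Q, Q, NULL, beta = 0, gamma = 0), 1e-10)

  # the topology term equals the weighted pairwise-difference identity
  V <- matrix(rnorm(3 * 15), 3, 15)
  W <- adjacency(gaussianAffinity(knnEdges(V, 3), V))
  gl <- graphLaplacian(W)
  Qr <- qr.Q(qr(matrix(rnorm(15 * 2), 15, 2)))
  pairSum <- 0
  for (i in 1:15) for (j in 1:15)
    pairSum <- pairSum + W[i, j] * sum((Qr[i, ] - Qr[j, ])^2)
  expect_equal(tpcaObjective(matrix(0, 3, 15), matrix(0, 3, 2), Qr, gl,
                             beta = 0, gamma = 2),
               2 * pairSum / 2, tolerance = 1e-10)

  expect_error(tpcaObjective(X2, X2 %*% Q, Q * 2, NULL), "orthonormal")
})

test_that("with beta = gamma = 0 the solver recovers the PCA subspace", {
  set.seed(42)
  X <- matrix(rnorm(30 * 60), 30, 60)
  cfg <- tpcaConfig(m = 5, beta = 0, gamma = 0,
                    reconstructionNorm = "frobenius", seed = 42)
  r <- solveTpca(X, NULL, cfg)
  Vtop <- svd(X)$v[, 1:5]
  # principal angles between the two 5-dim subspaces
  sv <- svd(crossprod(Vtop, embedding(r)))$d
  expect_lt(max(acos(pmin(sv, 1))), 1e-6)
})

test_that("objective trace is monotone and Q orthonormal across fixtures", {
  for (s in 1:6) {
    set.seed(s)
    N <- sample(20:60, 1)
    X <- matrix(abs(rnorm(10 * N)), 10, N)
    f <- knnFiltration(X, ks = c(4, 2))
    LP <- accumulateLaplacians(f, c(1, 1))
    for (norm in c("l21", "frobenius")) {
      r <- solveTpca(X, LP, tpcaConfig(m = 3, seed = s,
                                       reconstructionNorm = norm))
      expect_true(all(diff(objectiveTrace(r)) <= 1e-9))
      expect_lt(max(abs(crossprod(embedding(r)) - diag(3))), 1e-8)
    }
  }
})

test_that("strong topology weight collapses embeddings within components", {
  # two disconnected blobs; with large gamma the rows of Q become constant
  # within each blob relative to the between-blob separation
  set.seed(8)
  V <- cbind(matrix(rnorm(6 * 15, 0, 0.2), 6), matrix(rnorm(6 * 15, 30, 0.2), 6))
  f <- knnFiltration(V, ks = c(5))
  LP <- accumulateLaplacians(f, 1)
  r <- solveTpca(V, LP, tpcaConfig(m = 2, beta = 0, gamma = 1e6, seed = 8))
  Q <- embedding(r)
  lab <- rep(1:2, each = 15)
  within <- max(vapply(1:2, function(g) mean(apply(Q[lab == g, ], 2, sd)),
                       numeric(1)))
  between <- sqrt(sum((colMeans(Q[lab == 1, ]) - colMeans(Q[lab == 2, ]))^2))
  expect_lt(within / between, 1e-3)
})

test_that("solver is deterministic and equivariant to spot permutation", {
  set.seed(17)
  X <- matrix(abs(rnorm(8 * 30)), 8, 30)
  f <- knnFiltration(X, ks = c(4, 2))
  LP <- accumulateLaplacians(f, c(1, 1))
  cfg <- tpcaConfig(m = 3, seed = 17)
  r1 <- solveTpca(X, LP, cfg)
  r2 <- solveTpca(X, LP, cfg)
  expect_identical(embedding(r1), embedding(r2))

  p <- sample(30)
  fp <- knnFiltration(X[, p], ks = c(4, 2))
  rp <- solveTpca(X[, p], accumulateLaplacians(fp, c(1, 1)), cfg)
  # same subspace, rows permuted (columns may differ by sign/rotation only
  # when eigenvalues are distinct; compare projections)
  P1 <- tcrossprod(embedding(r1)[p, ])
  P2 <- tcrossprod(embedding(rp))
  expect_lt(max(abs(P1 - P2)), 1e-4)
})

test_that("each scale combination solved in batch equals the direct call", {
  set.seed(23)
  X <- matrix(abs(rnorm(10 * 40)), 10, 40)
  f <- knnFiltration(X, ks = c(6, 4, 2))
  cfg <- tpcaConfig(m = 4, seed = 23)
  embs <- embedAllScales(X, f, cfg)
  expect_length(embs, 7)
  direct <- solveTpca(X, accumulateLaplacians(f, c(0, 0, 1)), cfg)
  expect_equal(embedding(embs[[1]]), embedding(direct))
  expect_equal(embs[[1]]@zeta, c(0, 0, 1))
  # repeated batch call is bitwise identical
  embs2 <- embedAllScales(X, f, cfg)
  expect_identical(lapply(embs, embedding), lapply(embs2, embedding))
})

test_that("partial eigensolver agrees with the dense path", {
  set.seed(31)
  N <- 900; M <- 40
  X <- matrix(abs(rnorm(M * N)), M, N)
  f <- knnFiltration(X, ks = c(8, 4))
  LP <- laplacianMatrix(accumulateLaplacians(f, c(1, 1)))
  d1 <- runif(M, 0.1, 1); d2 <- runif(N, 0.1, 1)
  parts <- list(d2vec = d2, LPg = LP, Xw = sqrt(d1) * X)
  dense <- mcist:::.smallest_eigvecs(parts, m = 6, denseThreshold = 1000)
  set.seed(31)
  warm <- qr.Q(qr(matrix(rnorm(N * 6), N, 6)))
  part <- mcist:::.smallest_eigvecs(parts, m = 6, warmQ = warm,
                                    denseThreshold = 10, tolEig = 1e-10,
                                    maxSweeps = 200)
  expect_lt(max(abs(sort(dense$values) - sort(part$values))), 1e-6)
  sv <- svd(crossprod(dense$Q, part$Q))$d
  expect_lt(max(abs(sv - 1)), 1e-6)
})

test_that("solver rejects invalid inputs", {
  X <- matrix(1, 4, 5)
  expect_error(solveTpca(X, NULL, tpcaConfig(m = 10)), "exceeds")
  Xb <- X; Xb[2, 2] <- NA
  expect_error(solveTpca(Xb, NULL, tpcaConfig(m = 2)), "non-finite")
  expect_error(tpcaConfig(tol = 0), "tol")
  expect_error(tpcaConfig(beta = -1), "beta")
})
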