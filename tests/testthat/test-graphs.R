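test_that("kNN edges match brute-force enumeration and tie rules", {
  # collinear profiles at 0, 1, 3: nearest-neighbour union is a path
  V <- matrix(c(0, 1, 3), 1, 3)
  g <- knnEdges(V, k = 1)
  expect_equal(graphEdges(g), cbind(a = c(1L, 2L), b = c(2L, 3L)),
               ignore_attr = TRUE)

  # k = N-1 gives the complete graph
  set.seed(11)
  V2 <- matrix(rnorm(3 * 7), 3, 7)
  expect_equal(nrow(graphEdges(knnEdges(V2, 6))), choose(7, 2))

  # unit square, k = 1: each corner is equidistant to two others and must
  # pick the lower-indexed one
  # picks: 1->2, 2->1, 3->1, 4->2 (each lower-index equidistant neighbour)
  sq <- cbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  gs <- knnEdges(sq, k = 1)
  expect_equal(graphEdges(gs), cbind(a = c(1L, 1L, 2L), b = c(2L, 3L, 4L)),
               ignore_attr = TRUE)

  # randomized agreement with the all-pairs oracle
  for (s in 1:10) {
    set.seed(s)
    V3 <- matrix(rnorm(4 * 25), 4, 25)
    k <- sample(1:6, 1)
    expect_identical(edge_key(graphEdges(knnEdges(V3, k))),
                     edge_key(bf_knn_edges(V3, k)))
  }

  expect_error(knnEdges(V2, 7), "k must satisfy")
})

test_that("Gaussian affinities follow the kernel formula", {
  set.seed(2)
  V <- matrix(rnorm(3 * 8), 3, 8)
  V[, 2] <- V[, 1]                       # duplicate profile
  g <- knnEdges(V, 2)
  W <- gaussianAffinity(g, V, eta = 0.5)
  A <- adjacency(W)
  expect_equal(A[1, 2], 1)               # zero distance -> weight 1
  e <- graphEdges(g)
  d2 <- sum((V[, e[1, 1]] - V[, e[1, 2]])^2)
  expect_equal(A[e[1, 1], e[1, 2]], exp(-d2 / 0.5))
  # exact width: squared distance equal to eta gives exp(-1)
  Vp <- matrix(c(0, 1), 1, 2)
  Wp <- gaussianAffinity(knnEdges(Vp, 1), Vp, eta = 1)
  expect_equal(adjacency(Wp)[1, 2], exp(-1))
  # non-adjacent pairs carry weight zero
  nonEdges <- which(as.matrix(A) == 0, arr.ind = TRUE)
  expect_true(all(!edge_key(nonEdges) %in% edge_key(e)))
  expect_error(gaussianAffinity(g, V, eta = -1), "eta")
})

test_that("graph Laplacian L = D - W with its invariants", {
  # unit-weight path 0-1-2
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  L <- laplacianMatrix(graphLaplacian(A))
  expect_equal(as.matrix(L),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)),
               ignore_attr = TRUE)
  set.seed(6)
  V <- matrix(rnorm(3 * 12), 3, 12)
  W <- gaussianAffinity(knnEdges(V, 3), V)
  Lw <- laplacianMatrix(graphLaplacian(W))
  expect_lt(max(abs(Matrix::rowSums(Lw))), 1e-9)
  ev <- eigen(as.matrix(Lw), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # two disjoint unit edges -> zero eigenvalue of multiplicity 2
  A2 <- matrix(0, 4, 4); A2[1, 2] <- A2[2, 1] <- A2[3, 4] <- A2[4, 3] <- 1
  expect_equal(zero_eig_mult(laplacianMatrix(graphLaplacian(A2))), 2)
  Abad <- A; Abad[1, 2] <- 2
  expect_error(graphLaplacian(Abad), "symmetric")
})

test_that("trace identity Tr(Q'LQ) = half the weighted squared differences", {
  set.seed(9)
  V <- matrix(rnorm(4 * 20), 4, 20)
  W <- adjacency(gaussianAffinity(knnEdges(V, 4), V))
  L <- laplacianMatrix(graphLaplacian(W))
  Q <- matrix(rnorm(20 * 3), 20, 3)
  lhs <- sum(diag(crossprod(Q, as.matrix(L %*% Q))))
  rhs <- 0
  for (i in 1:20) for (j in 1:20)
    rhs <- rhs + W[i, j] * sum((Q[i, ] - Q[j, ])^2)
  expect_equal(lhs, rhs / 2, tolerance = 1e-10)
})

test_that("kNN filtration is nested with degree diagonals and Betti-0 zeros", {
  set.seed(21)
  V <- matrix(rnorm(3 * 5), 3, 5)
  f <- knnFiltration(V, ks = c(2, 1))
  e2 <- which(as.matrix(laplacianMatrix(f@laplacians[[1]])) < 0, arr.ind = TRUE)
  e1 <- which(as.matrix(laplacianMatrix(f@laplacians[[2]])) < 0, arr.ind = TRUE)
  expect_true(all(edge_key(e1) %in% edge_key(e2)))

  for (gl in filtrationLaplacians(f)) {
    L <- laplacianMatrix(gl)
    expect_lt(max(abs(Matrix::rowSums(L))), 1e-12)
    offdiag <- as.matrix(L); diag(offdiag) <- 0
    expect_true(all(offdiag %in% c(0, -1)))
  }

  # two well-separated blobs: the k=3 snapshot has exactly two components
  set.seed(22)
  blobs <- cbind(matrix(rnorm(2 * 10, 0, 0.1), 2), matrix(rnorm(2 * 10, 50, 0.1), 2))
  f2 <- knnFiltration(blobs, ks = c(3))
  expect_equal(zero_eig_mult(laplacianMatrix(f2@laplacians[[1]])), 2)

  expect_error(knnFiltration(V, ks = c(2, 2)), "strictly decreasing")
  expect_error(knnFiltration(V, ks = c(5, 2)), "max")
})

test_that("Laplacian construction is equivariant under spot permutations", {
  set.seed(30)
  V <- matrix(rnorm(4 * 18), 4, 18)
  p <- sample(18)
  f1 <- knnFiltration(V, ks = c(4, 2))
  f2 <- knnFiltration(V[, p], ks = c(4, 2))
  for (i in 1:2) {
    L1 <- as.matrix(laplacianMatrix(f1@laplacians[[i]]))
    L2 <- as.matrix(laplacianMatrix(f2@laplacians[[i]]))
    expect_equal(L2, L1[p, p], ignore_attr = TRUE)
  }
})

test_that("accumulated Laplacian is the exact weighted sum and PSD", {
  set.seed(13)
  V <- matrix(rnorm(5 * 50), 5, 50)
  f <- knnFiltration(V, ks = c(6, 4, 2))
  L1 <- accumulateLaplacians(f, c(1, 0, 0))
  expect_equal(as.matrix(laplacianMatrix(L1)),
               as.matrix(laplacianMatrix(f@laplacians[[1]])))
  Lall <- accumulateLaplacians(f, c(1, 1, 1))
  expect_equal(as.matrix(laplacianMatrix(Lall)),
               Reduce(`+`, lapply(f@laplacians, function(g) as.matrix(g@L))))
  for (z in zetaGrid(3)) {
    ev <- eigen(as.matrix(laplacianMatrix(accumulateLaplacians(f, z))),
                symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
  expect_error(accumulateLaplacians(f, c(0, 0, 0)), "empty scale combination")
  expect_error(accumulateLaplacians(f, c(0.5, 0, 0)), "binary")
  expect_silent(accumulateLaplacians(f, c(0.5, 0, 0), allowReal = TRUE))
})

test_that("zeta grid enumerates all non-zero binary vectors in fixed order", {
  expect_equal(zetaGrid(2), list(c(0, 1), c(1, 0), c(1, 1)))
  expect_length(zetaGrid(4), 15)
  expect_identical(zetaGrid(4), zetaGrid(4))
  expect_error(zetaGrid(0), "p must be")
})

test_that("graphs and weights export as edge-list TSVs", {
  set.seed(14)
  V <- matrix(rnorm(3 * 6), 3, 6)
  g <- knnEdges(V, 2)
  p <- file.path(tempdir(), "edges.tsv")
  writeEdgeList(g, p)
  df <- read.delim(p)
  expect_equal(nrow(df), nrow(graphEdges(g)))
  writeEdgeList(gaussianAffinity(g, V), p)
  dfw <- read.delim(p)
  expect_true(all(dfw$weight > 0 & dfw$weight <= 1))
})
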