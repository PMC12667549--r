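test_that("gmm clustering recovers well-separated blobs exactly", {
  set.seed(1)
  F1 <- rbind(matrix(rnorm(40 * 2, 0, 0.1), ncol = 2),
              matrix(rnorm(40 * 2, 10, 0.1), ncol = 2))
  planted <- rep(0:1, each = 40)
  lab <- clusterEmbedding(F1, "gmm", 2, seed = 4)
  expect_equal(ari(clusterLabels(lab), planted), 1)
  # determinism
  lab2 <- clusterEmbedding(F1, "gmm", 2, seed = 4)
  expect_identical(clusterLabels(lab), clusterLabels(lab2))
  # boundary: one cluster per point is the trivial partition
  triv <- clusterEmbedding(F1[1:5, ], "gmm", 5, seed = 1)
  expect_equal(sort(clusterLabels(triv)), 0:4)
  expect_error(clusterEmbedding(F1, "gmm", 1000), "exceed")
})

test_that("leiden clustering hits the requested count deterministically", {
  set.seed(2)
  F1 <- do.call(rbind, lapply(c(0, 8, 16), function(mu)
    matrix(rnorm(30 * 3, mu, 0.3), ncol = 3)))
  planted <- rep(0:2, each = 30)
  lab <- clusterEmbedding(F1, "leiden", 3, seed = 7)
  expect_equal(length(unique(clusterLabels(lab))), 3)
  expect_equal(ari(clusterLabels(lab), planted), 1)
  expect_identical(clusterLabels(clusterEmbedding(F1, "leiden", 3, seed = 7)),
                   clusterLabels(lab))
})

test_that("co-association counts pair agreements exactly", {
  l1 <- ClusterLabels(letters[1:4], c(0, 0, 1, 1))
  C <- coAssociationMatrix(coAssociation(list(l1, l1, l1)))
  expect_equal(C, rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                        c(0, 0, 1, 1), c(0, 0, 1, 1)), ignore_attr = TRUE)

  ls <- list(c(0L, 0L, 1L), c(0L, 1L, 1L))
  C2 <- coAssociationMatrix(coAssociation(ls))
  expect_equal(C2[1, 2], 0.5)
  expect_equal(C2[2, 3], 0.5)
  expect_equal(C2[1, 3], 0)
  expect_true(all(diag(C2) == 1))

  # brute-force equivalence on random ensembles
  for (s in 1:5) {
    set.seed(s)
    lsr <- lapply(1:4, function(i) sample(0:2, 12, replace = TRUE))
    expect_equal(coAssociationMatrix(coAssociation(lsr)),
                 bf_coassociation(lsr))
  }
  expect_error(coAssociation(list(1:3, 1:4)), "mismatched")
  expect_error(coAssociation(list()), "at least one")
})

test_that("consensus clustering recovers clean block structure", {
  C <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  dom <- consensusCluster(new("CoAssociation", Cmat = C), 2)
  expect_equal(clusterLabels(dom), c(0L, 0L, 1L, 1L))
  # n = N yields singletons
  singles <- consensusCluster(new("CoAssociation", Cmat = diag(4)), 4)
  expect_equal(sort(clusterLabels(singles)), 0:3)
  # tie case from the 2-member toy: average linkage must deterministically
  # pick one of the two valid first merges ({0,1} or {1,2} at distance 0.5)
  Ct <- coAssociation(list(c(0L, 0L, 1L), c(0L, 1L, 1L)))
  d1 <- clusterLabels(consensusCluster(Ct, 2))
  expect_true(identical(d1, c(0L, 0L, 1L)) || identical(d1, c(0L, 1L, 1L)))
  expect_identical(clusterLabels(consensusCluster(Ct, 2)), d1)
  expect_error(consensusCluster(Ct, 10), "exceed")
})

test_that("consensus is invariant to member order and spot relabeling", {
  set.seed(33)
  ls <- lapply(1:5, function(i) sample(0:2, 20, replace = TRUE))
  d1 <- clusterLabels(consensusCluster(coAssociation(ls), 3))
  d2 <- clusterLabels(consensusCluster(coAssociation(rev(ls)), 3))
  expect_equal(ari(d1, d2), 1)
  p <- sample(20)
  dp <- clusterLabels(consensusCluster(coAssociation(lapply(ls, function(l) l[p])), 3))
  expect_equal(ari(dp, d1[p]), 1)
})

test_that("RSI matches hand evaluation and favours true structure", {
  # two zero-diameter clusters far apart: perfect score
  F0 <- matrix(rep(c(0, 100), each = 3), ncol = 1)
  r0 <- rsi(F0, c(0, 0, 0, 1, 1, 1))
  expect_equal(rsiValue(r0), 1)

  # four points on a line at 0, 1, 10, 11 labelled [0,0,1,1]:
  # residues [1, 19/21, 19/21, 1], similarities all 10/11
  r1 <- rsi(matrix(c(0, 1, 10, 11), ncol = 1), c(0, 0, 1, 1))
  expect_equal(r1@residue, c(1, 19/21, 19/21, 1))
  expect_equal(r1@similarity, rep(10/11, 4))
  expect_equal(rsiValue(r1), mean((c(1, 19/21, 19/21, 1) + 10/11) / 2))

  expect_error(rsi(F0, rep(0, 6)), "one cluster")

  # planted blobs score above random labels in at least 19/20 seeds
  wins <- 0
  for (s in 1:20) {
    set.seed(s)
    Fb <- rbind(matrix(rnorm(30, 0, 1), ncol = 2),
                matrix(rnorm(30, 6, 1), ncol = 2))
    truth <- rep(0:1, each = 15)
    if (rsiValue(rsi(Fb, truth)) > rsiValue(rsi(Fb, sample(truth))))
      wins <- wins + 1
  }
  expect_gte(wins, 19)
})

test_that("RSI selection takes the first maximum", {
  set.seed(3)
  Fgood <- rbind(matrix(rnorm(20, 0, 0.1), ncol = 2),
                 matrix(rnorm(20, 10, 0.1), ncol = 2))
  Fbad <- matrix(rnorm(40), ncol = 2)
  labs <- rep(0:1, each = 10)
  expect_equal(selectByRsi(list(list(F = Fgood, labels = labs))), 1)
  expect_equal(selectByRsi(list(list(F = Fgood, labels = labs),
                                list(F = Fbad, labels = labs))), 1)
  expect_equal(selectByRsi(list(list(F = Fbad, labels = labs),
                                list(F = Fgood, labels = labs))), 2)
  # exact tie -> lowest index
  expect_equal(selectByRsi(list(list(F = Fgood, labels = labs),
                                list(F = Fgood, labels = labs))), 1)
  expect_error(selectByRsi(list()), "empty")
})

test_that("NMI and ARI match contingency-table evaluation", {
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(ari(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 0, 0, 0)), 0)
  # crossed 2x2 design: MI = 0, ARI = -1/2 by direct formula
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(ari(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  # ARI agrees with the mclust implementation on random labelings
  for (s in 1:10) {
    set.seed(s)
    a <- sample(0:3, 30, replace = TRUE)
    b <- sample(0:2, 30, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_error(nmi(1:3, 1:4), "lengths")
})

test_that("the orchestrated pipeline is deterministic and id-safe", {
  ds <- small_synth(5)
  X <- selectHvg(normalizeLog(qcFilter(ds@expression, 1, 1)), 80)
  cfg <- tpcaConfig(m = 10, seed = 5)
  r1 <- runMcist(X, ds@coords, nDomains = 5, cfg = cfg, seed = 5,
                 ks = c(8, 5, 3))
  r2 <- runMcist(X, ds@coords, nDomains = 5, cfg = cfg, seed = 5,
                 ks = c(8, 5, 3))
  expect_identical(clusterLabels(r1), clusterLabels(r2))
  expect_identical(coAssociationMatrix(r1@coAssociation),
                   coAssociationMatrix(r2@coAssociation))
  expect_length(r1@memberLabelsets, 7)
  expect_equal(length(unique(clusterLabels(r1))), 5)

  # rsi_select mode returns a selected member and its labels
  r3 <- runMcist(X, ds@coords, nDomains = 5, cfg = cfg, seed = 5,
                 ks = c(8, 5, 3), mode = "rsi_select")
  expect_false(is.na(r3@selectedEmbedding))
  expect_identical(clusterLabels(domains(r3)),
                   clusterLabels(r3@memberLabelsets[[r3@selectedEmbedding]]))
  expect_length(r3@rsiValues, 7)

  # mismatched ids fail loudly
  badCoords <- SpatialCoords(rev(spotIds(ds@coords)), coordsXY(ds@coords))
  expect_error(runMcist(X, badCoords, nDomains = 5, cfg = cfg, seed = 5),
               "inconsistent spot ids")
})
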