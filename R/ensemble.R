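#' @importFrom mclust Mclust mclustBIC
#' @importFrom igraph graph_from_adjacency_matrix cluster_leiden membership
NULL

.child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * i) %% .Machine$integer.max)
}

.snn_graph <- function(Fmat, kSnn = 15L) {
  n <- nrow(Fmat)
  kSnn <- min(kSnn, n - 1L)
  ord <- .neighbour_order(.spot_sqdist(t(Fmat)))
  # binary membership of each spot's closed neighbourhood {i} + kNN(i)
  B <- Matrix::sparseMatrix(
    i = rep(seq_len(n), kSnn + 1L),
    j = c(seq_len(n), as.vector(ord[, seq_len(kSnn), drop = FALSE])),
    x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(B)   # |closed(i) intersect closed(j)|
  # shared-nearest-neighbour Jaccard weights on the kNN union edges
  e <- .edges_from_prefix(ord[, seq_len(kSnn), drop = FALSE], kSnn)
  s <- shared[cbind(e[, 1], e[, 2])]
  w <- s / (2 * (kSnn + 1L) - s)
  keep <- w > 0
  A <- Matrix::sparseMatrix(i = c(e[keep, 1], e[keep, 2]),
                            j = c(e[keep, 2], e[keep, 1]),
                            x = c(w[keep], w[keep]), dims = c(n, n))
  igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

.leiden_at <- function(g, resolution, seed) {
  set.seed(seed)
  igraph::membership(igraph::cluster_leiden(
    g, objective_function = "modularity", resolution = resolution,
    n_iterations = 3))
}

.leiden_fixed_k <- function(Fmat, nClusters, seed, maxSteps = 30L) {
  g <- .snn_graph(Fmat)
  lo <- 1e-4; hi <- 1
  memb <- .leiden_at(g, hi, seed)
  steps <- 0L
  while (max(memb) < nClusters && steps < maxSteps) {
    hi <- hi * 2; memb <- .leiden_at(g, hi, seed); steps <- steps + 1L
  }
  best <- memb
  for (s in seq_len(maxSteps - steps)) {
    mid <- (lo + hi) / 2
    memb <- .leiden_at(g, mid, seed)
    if (abs(max(memb) - nClusters) < abs(max(best) - nClusters)) best <- memb
    if (max(memb) == nClusters) { best <- memb; break }
    if (max(memb) < nClusters) lo <- mid else hi <- mid
  }
  if (max(best) != nClusters)
    warning(sprintf("leiden: requested %d clusters, achieved %d (closest)",
                    nClusters, max(best)))
  as.integer(best)
}

.gmm_labels <- function(Fmat, nClusters, seed) {
  set.seed(seed)
  d <- ncol(Fmat)
  models <- if (d > 1) c("VVV", "EEE", "EII") else c("V", "E")
  fit <- NULL
  for (mn in models) {
    fit <- suppressWarnings(
      mclust::Mclust(Fmat, G = nClusters, modelNames = mn, verbose = FALSE))
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {       # degenerate geometry; fall back to k-means
    km <- stats::kmeans(Fmat, centers = nClusters, nstart = 10)
    return(as.integer(km$cluster))
  }
  as.integer(fit$classification)
}

#' Cluster an aligned embedding
#'
#' `method = "gmm"` fits a finite Gaussian mixture by model-based EM
#' (mclust; full covariance first, falling back to more constrained models
#' for degenerate geometry). `method = "leiden"` builds a
#' shared-nearest-neighbour graph (Jaccard weights over 15-NN lists) and
#' runs Leiden community detection, with the resolution found by bisection
#' (at most 30 steps) so the community count matches `nClusters`; if the
#' exact count is unreachable the closest achievable partition is returned
#' with a warning. Both paths are deterministic under `seed`.
#'
#' @param F N x d feature matrix (or [AlignedEmbedding-class]).
#' @param method `"gmm"` or `"leiden"`.
#' @param nClusters requested cluster count (<= N).
#' @param seed integer seed.
#' @param spotIds optional ids for the result (defaults to row numbers).
#' @return A [ClusterLabels-class] (labels 0-based).
#' @export
clusterEmbedding <- function(F, method = c("gmm", "leiden"), nClusters,
                             seed = 0, spotIds = NULL) {
  method <- match.arg(method)
  if (is(F, "AlignedEmbedding")) F <- alignedFeatures(F)
  F <- as.matrix(F)
  n <- nrow(F)
  if (nClusters > n) stop("nClusters must not exceed the number of spots")
  if (is.null(spotIds)) spotIds <- as.character(seq_len(n))
  if (nClusters == n)               # trivial partition, documented boundary
    return(ClusterLabels(spotIds, seq_len(n) - 1L))
  lab <- switch(method,
    gmm = .gmm_labels(F, nClusters, seed),
    leiden = .leiden_fixed_k(F, nClusters, seed))
  ClusterLabels(spotIds, lab)
}

#' Co-association matrix of an ensemble of label sets
#'
#' `C[i,j]` is the fraction of member label sets in which spots i and j
#' share a cluster; the diagonal is exactly 1.
#'
#' @param labelsets list of [ClusterLabels-class] (or integer vectors), all
#'   of one length.
#' @return A [CoAssociation-class].
#' @export
coAssociation <- function(labelsets) {
  if (!length(labelsets)) stop("at least one label set required")
  labs <- lapply(labelsets, function(l)
    if (is(l, "ClusterLabels")) clusterLabels(l) else as.integer(l))
  n <- length(labs[[1]])
  if (any(vapply(labs, length, 1L) != n))
    stop("label sets have mismatched lengths")
  C <- matrix(0, n, n)
  for (l in labs) C <- C + outer(l, l, "==")
  C <- C / length(labs)
  diag(C) <- 1
  new("CoAssociation", Cmat = C)
}

#' Consensus clustering of a co-association matrix
#'
#' Agglomerative clustering on the consensus distance `1 - C`, cut at
#' `nDomains` clusters. The merge order of `stats::hclust` is deterministic
#' for a fixed input, which fixes the tie-breaking rule.
#'
#' @param C a [CoAssociation-class].
#' @param nDomains requested number of domains.
#' @param linkage `"average"` (default), `"complete"` or `"ward.D2"`.
#' @param spotIds optional ids for the result.
#' @return A [ClusterLabels-class].
#' @export
consensusCluster <- function(C, nDomains, linkage = c("average", "complete", "ward.D2"),
                             spotIds = NULL) {
  linkage <- match.arg(linkage)
  Cm <- if (is(C, "CoAssociation")) coAssociationMatrix(C) else as.matrix(C)
  n <- nrow(Cm)
  if (nDomains > n) stop("nDomains must not exceed the number of spots")
  if (is.null(spotIds)) spotIds <- as.character(seq_len(n))
  hc <- stats::hclust(stats::as.dist(1 - Cm), method = linkage)
  ClusterLabels(spotIds, stats::cutree(hc, k = nDomains))
}

#' Residue-similarity index of a labelled embedding
#'
#' A label-aware, ground-truth-free embedding quality score. With
#' `d_max` the largest pairwise distance and
#' `R_i = sum over out-of-class j of d(i, j)`:
#' residue_i = `R_i / max_i R_i` (between-class separation), similarity_i =
#' mean over same-class j of `1 - d(i,j)/d_max` (within-class cohesion;
#' singletons score 1), and `rsi = mean_i (residue_i + similarity_i)/2`.
#'
#' @param F N x d feature matrix (or [AlignedEmbedding-class]).
#' @param labels a [ClusterLabels-class] (or integer vector) with >= 2
#'   classes.
#' @return An [RsiReport-class].
#' @export
rsi <- function(F, labels) {
  if (is(F, "AlignedEmbedding")) F <- alignedFeatures(F)
  lab <- if (is(labels, "ClusterLabels")) clusterLabels(labels)
         else as.integer(labels)
  F <- as.matrix(F)
  if (length(lab) != nrow(F)) stop("labels length must match feature rows")
  if (length(unique(lab)) < 2L) stop("RSI undefined for one cluster")
  D <- as.matrix(dist(F))
  dmax <- max(D)
  if (dmax == 0) stop("RSI degenerate: all points identical")
  n <- nrow(F)
  same <- outer(lab, lab, "==")
  Rraw <- rowSums(D * !same)
  residue <- Rraw / max(Rraw)
  S <- 1 - D / dmax
  nSame <- rowSums(same) - 1L
  similarity <- ifelse(nSame > 0,
                       (rowSums(S * same) - 1) / pmax(nSame, 1L), 1)
  new("RsiReport", rsi = mean((residue + similarity) / 2),
      residue = unname(residue), similarity = unname(similarity))
}

#' Select the candidate embedding maximizing RSI
#'
#' @param candidates list of `list(F =, labels =)` pairs.
#' @return 1-based index of the maximal-RSI candidate (ties: lowest index).
#' @export
selectByRsi <- function(candidates) {
  if (!length(candidates)) stop("empty candidate list")
  vals <- vapply(candidates, function(c) rsiValue(rsi(c$F, c$labels)),
                 numeric(1))
  which.max(vals)   # which.max takes the first maximum: lowest index on ties
}

.contingency <- function(a, b) {
  table(factor(a, levels = sort(unique(a))), factor(b, levels = sort(unique(b))))
}

#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies; 1 for identical partitions, 0 when one labeling is constant.
#'
#' @param a,b [ClusterLabels-class] or integer vectors of equal length.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(a, b) {
  la <- if (is(a, "ClusterLabels")) clusterLabels(a) else as.integer(a)
  lb <- if (is(b, "ClusterLabels")) clusterLabels(b) else as.integer(b)
  if (length(la) != length(lb)) stop("labelings have different lengths")
  n <- length(la)
  tab <- .contingency(la, lb)
  pij <- tab / n
  pi <- rowSums(pij); pj <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  ha <- -sum(pi[pi > 0] * log(pi[pi > 0]))
  hb <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (ha == 0 && hb == 0) return(1)
  if (mi <= 0) return(0)
  mi / ((ha + hb) / 2)
}

#' Adjusted Rand index between two labelings
#'
#' The permutation-model-corrected Rand index; 1 for identical partitions,
#' 0 in expectation for independent ones.
#'
#' @param a,b [ClusterLabels-class] or integer vectors of equal length.
#' @return ARI (<= 1).
#' @export
ari <- function(a, b) {
  la <- if (is(a, "ClusterLabels")) clusterLabels(a) else as.integer(a)
  lb <- if (is(b, "ClusterLabels")) clusterLabels(b) else as.integer(b)
  if (length(la) != length(lb)) stop("labelings have different lengths")
  n <- length(la)
  tab <- .contingency(la, lb)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  stot <- choose(n, 2)
  expected <- sa * sb / stot
  denom <- (sa + sb) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

#' Run the full multiscale consensus pipeline
#'
#' Orchestrates spatial-domain detection end to end: kNN-induced filtration
#' of the expression space ([knnFiltration()]), one topological PCA
#' embedding per scale combination ([embedAllScales()]), CCA alignment of
#' each with the spatial embedding ([alignAll()]), clustering of every
#' aligned embedding ([clusterEmbedding()], child seeds derived from
#' `seed`), and either co-association consensus
#' (`mode = "ensemble"`: [coAssociation()] + [consensusCluster()]) or
#' selection of the single RSI-maximizing embedding
#' (`mode = "rsi_select"`), whose cluster labels become the domains.
#' Fully deterministic under `seed`.
#'
#' @param X preprocessed [ExpressionMatrix-class] (log-transformed or HVG
#'   subset), or raw counts with `preprocess = TRUE`.
#' @param coords [SpatialCoords-class]; required unless `spatialEmbedding`
#'   is given.
#' @param nDomains requested number of spatial domains.
#' @param spatialEmbedding optional [SpatialEmbedding-class] (e.g. loaded
#'   from a deep-learning encoder's output); defaults to
#'   [baselineSpatialEmbedding()].
#' @param mode `"ensemble"` (default) or `"rsi_select"`.
#' @param method clustering method, `"leiden"` (default) or `"gmm"`.
#' @param ks filtration scales (default `c(15, 12, 9, 6)`).
#' @param cfg [TpcaConfig-class] for the embeddings (seed overridden by
#'   `seed`).
#' @param kSpatial,rounds,nComp baseline encoder settings.
#' @param linkage consensus linkage.
#' @param seed master seed.
#' @param preprocess run [preprocessExpression()] first.
#' @param returnEmbeddings keep the aligned embeddings in the result (for
#'   downstream RSI/inspection).
#' @param verbose log stage progress.
#' @return A [ConsensusResult-class].
#' @export
runMcist <- function(X, coords = NULL, nDomains, spatialEmbedding = NULL,
                     mode = c("ensemble", "rsi_select"),
                     method = c("leiden", "gmm"), ks = c(15, 12, 9, 6),
                     cfg = tpcaConfig(), kSpatial = 6, rounds = 2, nComp = 30,
                     linkage = "average", seed = 0, preprocess = FALSE,
                     returnEmbeddings = FALSE, verbose = FALSE) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  say <- function(...) if (verbose) message(sprintf(...))
  stopifnot(is(X, "ExpressionMatrix"))
  if (preprocess) {
    say("preprocessing %d x %d raw counts", nrow(X), ncol(X))
    X <- preprocessExpression(X)
    if (!is.null(coords)) {
      keep <- match(spotIds(X), spotIds(coords))
      if (any(is.na(keep))) stop("coords do not cover the expression spots")
      coords <- SpatialCoords(spotIds(coords)[keep], coordsXY(coords)[keep, , drop = FALSE])
    }
  }
  if (!exprState(X) %in% c("log_transformed", "hvg_subset"))
    stop("X must be preprocessed (log_transformed/hvg_subset) or preprocess=TRUE")
  if (is.null(spatialEmbedding)) {
    if (is.null(coords)) stop("either coords or spatialEmbedding is required")
    if (!identical(spotIds(X), spotIds(coords)))
      stop("inconsistent spot ids between expression and coordinates")
    say("baseline spatial encoder (k=%d, rounds=%d, %d comps)",
        kSpatial, rounds, nComp)
    spatialEmbedding <- baselineSpatialEmbedding(X, coords, kSpatial, rounds,
                                                 nComp, seed = seed)
  } else if (!identical(spotIds(X), spotIds(spatialEmbedding))) {
    stop("inconsistent spot ids between expression and spatial embedding")
  }
  cfg@seed <- as.integer(seed)
  say("kNN filtration at scales %s", paste(ks, collapse = ","))
  filt <- knnFiltration(X, ks)
  say("embedding %d scale combinations (m=%d)", 2^length(ks) - 1, cfg@m)
  embs <- embedAllScales(X, filt, cfg)
  say("CCA alignment")
  aligned <- alignAll(spatialEmbedding, embs)
  say("clustering %d aligned embeddings (%s)", length(aligned), method)
  members <- lapply(seq_along(aligned), function(i)
    clusterEmbedding(aligned[[i]], method = method, nClusters = nDomains,
                     seed = .child_seed(seed, i), spotIds = spotIds(X)))
  rsiVals <- numeric(0)
  selected <- NA_integer_
  if (mode == "ensemble") {
    say("co-association consensus")
    C <- coAssociation(members)
    dom <- consensusCluster(C, nDomains, linkage = linkage,
                            spotIds = spotIds(X))
  } else {
    say("RSI selection")
    rsiVals <- vapply(seq_along(aligned), function(i)
      rsiValue(rsi(aligned[[i]], members[[i]])), numeric(1))
    selected <- which.max(rsiVals)
    dom <- members[[selected]]
    C <- NULL
  }
  res <- new("ConsensusResult", domains = dom, memberLabelsets = members,
             coAssociation = C, selectedEmbedding = selected,
             rsiValues = rsiVals,
             config = list(nDomains = nDomains, mode = mode, method = method,
                           ks = ks, m = cfg@m, beta = cfg@beta,
                           gamma = cfg@gamma, kSpatial = kSpatial,
                           rounds = rounds, nComp = nComp, linkage = linkage,
                           seed = seed))
  if (returnEmbeddings) attr(res, "alignedEmbeddings") <- aligned
  res
}
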