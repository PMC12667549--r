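#' @import methods
#' @importFrom Matrix Matrix sparseMatrix Diagonal rowSums colSums t readMM writeMM crossprod tcrossprod
#' @importFrom stats dist prcomp rnbinom rlnorm runif rbinom hclust cutree as.dist median var cor sd kmeans
NULL

.EXPR_STATES <- c("raw_counts", "normalized", "log_transformed", "hvg_subset")

#' Gene-by-spot expression matrix with processing state
#'
#' Canonical container for an M-gene by N-spot expression matrix. Rows are
#' genes, columns are spots/cells (the field's X in R^{M x N}). The `state`
#' tag records how far the matrix has moved along the fixed processing chain
#' `raw_counts -> normalized -> log_transformed -> hvg_subset`; operations
#' check it so that, e.g., log-normalization cannot be applied twice.
#'
#' @slot values numeric matrix or sparse `Matrix` (genes x spots), non-negative.
#' @slot geneIds character vector of unique gene identifiers (length M).
#' @slot spotIds character vector of unique spot identifiers (length N).
#' @slot state one of `"raw_counts"`, `"normalized"`, `"log_transformed"`,
#'   `"hvg_subset"`.
#' @export
setClass("ExpressionMatrix",
  representation(values = "ANY", geneIds = "character",
                 spotIds = "character", state = "character"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  if (!(is.matrix(v) || is(v, "Matrix")))
    return("values must be a base matrix or a Matrix")
  if (length(object@geneIds) != nrow(v))
    return("geneIds length does not match nrow(values)")
  if (length(object@spotIds) != ncol(v))
    return("spotIds length does not match ncol(values)")
  if (anyDuplicated(object@geneIds))
    return(sprintf("duplicate gene ids: %s",
                   paste(unique(object@geneIds[duplicated(object@geneIds)]), collapse = ", ")))
  if (anyDuplicated(object@spotIds))
    return(sprintf("duplicate spot ids: %s",
                   paste(unique(object@spotIds[duplicated(object@spotIds)]), collapse = ", ")))
  if (length(object@state) != 1L || !object@state %in% .EXPR_STATES)
    return(sprintf("state must be one of: %s", paste(.EXPR_STATES, collapse = ", ")))
  mn <- if (is(v, "sparseMatrix")) min(0, min(v@x, 0)) else min(v)
  if (is.finite(mn) && mn < 0) return("expression values must be non-negative")
  if (object@state == "raw_counts") {
    x <- if (is(v, "sparseMatrix")) v@x else as.vector(v)
    if (length(x) && any(abs(x - round(x)) > 1e-8))
      return("state 'raw_counts' requires integer values")
  }
  TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values genes x spots matrix (base or sparse).
#' @param geneIds,spotIds identifiers; default to dimnames when present.
#' @param state processing-state tag (default `"raw_counts"`).
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(values, geneIds = rownames(values),
                             spotIds = colnames(values), state = "raw_counts") {
  if (is.null(geneIds)) geneIds <- paste0("g", seq_len(nrow(values)))
  if (is.null(spotIds)) spotIds <- paste0("s", seq_len(ncol(values)))
  new("ExpressionMatrix", values = values, geneIds = as.character(geneIds),
      spotIds = as.character(spotIds), state = state)
}

#' Spatial coordinates paired to an expression matrix
#'
#' @slot spotIds character, aligned (set and order) to the paired
#'   [ExpressionMatrix-class] spot ids.
#' @slot xy N x 2 numeric matrix of spot positions.
#' @export
setClass("SpatialCoords", representation(spotIds = "character", xy = "matrix"))

setValidity("SpatialCoords", function(object) {
  if (ncol(object@xy) != 2L) return("xy must have exactly two columns")
  if (nrow(object@xy) != length(object@spotIds))
    return("spotIds length does not match nrow(xy)")
  if (anyDuplicated(object@spotIds)) return("duplicate spot ids")
  if (any(!is.finite(object@xy))) return("non-finite coordinates")
  TRUE
})

#' @rdname SpatialCoords-class
#' @param spotIds,xy see slots.
#' @export
SpatialCoords <- function(spotIds, xy) {
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  new("SpatialCoords", spotIds = as.character(spotIds), xy = xy)
}

#' Undirected k-nearest-neighbour graph over spots
#'
#' Edges are the union-symmetrized kNN relation: (i, j) is an edge iff j is
#' among the k nearest neighbours of i or i is among the k nearest of j.
#'
#' @slot n number of spots.
#' @slot k neighbour count.
#' @slot metric distance metric tag (`"euclidean"`).
#' @slot edges integer matrix with two columns (i < j), one row per edge.
#' @export
setClass("KnnGraph",
  representation(n = "integer", k = "integer", metric = "character",
                 edges = "matrix"))

setValidity("KnnGraph", function(object) {
  e <- object@edges
  if (ncol(e) != 2L) return("edges must have two columns")
  if (nrow(e)) {
    if (any(e[, 1] >= e[, 2])) return("edges must satisfy i < j (no self-loops)")
    if (min(e) < 1L || max(e) > object@n) return("edge indices out of range")
    if (anyDuplicated(e)) return("duplicate edges")
  }
  TRUE
})

#' Gaussian-kernel weighted adjacency on a KnnGraph
#'
#' @slot n spot count.
#' @slot eta Gaussian kernel width (the squared-distance scale).
#' @slot W symmetric N x N sparse matrix; `W[i,j] = exp(-d_ij^2/eta)` on
#'   edges, 0 elsewhere, zero diagonal.
#' @export
setClass("WeightedAdjacency",
  representation(n = "integer", eta = "numeric", W = "ANY"))

setValidity("WeightedAdjacency", function(object) {
  W <- object@W
  if (nrow(W) != object@n || ncol(W) != object@n) return("W dimension mismatch")
  if (object@eta <= 0) return("eta must be positive")
  if (max(abs(W - Matrix::t(W))) > 1e-12) return("W must be symmetric")
  if (any(Matrix::diag(W) != 0)) return("W must have zero diagonal")
  x <- if (is(W, "sparseMatrix")) W@x else as.vector(W)
  if (length(x) && (min(x) < 0 || max(x) > 1 + 1e-12))
    return("edge weights must lie in (0, 1]")
  TRUE
})

#' Graph Laplacian L = D - W
#'
#' @slot n spot count.
#' @slot L symmetric N x N matrix with zero row sums, non-positive
#'   off-diagonals; positive semi-definite.
#' @export
setClass("GraphLaplacian", representation(n = "integer", L = "ANY"))

setValidity("GraphLaplacian", function(object) {
  L <- object@L
  if (nrow(L) != object@n || ncol(L) != object@n) return("L dimension mismatch")
  if (max(abs(Matrix::rowSums(L))) > 1e-9 * max(1, object@n))
    return("Laplacian rows must sum to zero")
  if (max(abs(L - Matrix::t(L))) > 1e-9) return("Laplacian must be symmetric")
  TRUE
})

#' kNN-induced filtration of persistent (order-0) Laplacians
#'
#' One unweighted graph Laplacian per neighbour count k, over a strictly
#' decreasing scale list; smaller-k edge sets are nested inside larger-k ones.
#'
#' @slot ks strictly decreasing integer vector (default scales 15, 12, 9, 6).
#' @slot laplacians list of [GraphLaplacian-class], one per k.
#' @slot n spot count shared by all snapshots.
#' @export
setClass("LaplacianFiltration",
  representation(ks = "integer", laplacians = "list", n = "integer"))

setValidity("LaplacianFiltration", function(object) {
  if (length(object@ks) != length(object@laplacians))
    return("one Laplacian required per k")
  if (length(object@ks) > 1 && any(diff(object@ks) >= 0))
    return("ks must be strictly decreasing")
  TRUE
})

#' Accumulated multiscale Laplacian L_P
#'
#' The zeta-weighted sum of filtration Laplacians, `L_P = sum_k zeta_k L^k`,
#' a single positive semi-definite regularizer encoding multiscale
#' connectivity.
#'
#' @slot zeta binary (by default) weight per filtration scale; not all zero.
#' @slot ks the scales the weights refer to.
#' @slot LP the summed N x N Laplacian.
#' @export
setClass("AccumulatedLaplacian",
  representation(zeta = "numeric", ks = "integer", LP = "ANY"))

setValidity("AccumulatedLaplacian", function(object) {
  if (length(object@zeta) != length(object@ks))
    return("zeta length must match number of scales")
  if (all(object@zeta == 0)) return("empty scale combination (zeta all zero)")
  if (any(object@zeta < 0)) return("zeta weights must be non-negative")
  TRUE
})

#' Configuration for the topological PCA solver
#'
#' @slot m embedding dimension.
#' @slot beta sparsity (L2,1 on Q) weight.
#' @slot gamma topology (Laplacian trace) weight.
#' @slot maxIter maximum IRLS iterations.
#' @slot tol relative objective-change convergence tolerance.
#' @slot eps IRLS smoothing floor for row norms.
#' @slot reconstructionNorm `"l21"` or `"frobenius"`.
#' @slot seed integer seed.
#' @export
setClass("TpcaConfig",
  representation(m = "integer", beta = "numeric", gamma = "numeric",
                 maxIter = "integer", tol = "numeric", eps = "numeric",
                 reconstructionNorm = "character", seed = "integer"))

setValidity("TpcaConfig", function(object) {
  if (object@m < 1L) return("m must be >= 1")
  if (object@beta < 0 || object@gamma < 0) return("beta and gamma must be >= 0")
  if (object@tol <= 0 || object@eps <= 0) return("tol and eps must be positive")
  if (!object@reconstructionNorm %in% c("l21", "frobenius"))
    return("reconstructionNorm must be 'l21' or 'frobenius'")
  TRUE
})

#' Construct a TpcaConfig
#'
#' Defaults follow the method's published operating point: `beta = gamma = 1`
#' (performance is reported stable across many orders of magnitude), an
#' m = 50 dimensional embedding, and an L2,1 reconstruction norm.
#'
#' @param m,beta,gamma,maxIter,tol,eps,reconstructionNorm,seed see slots.
#' @return A [TpcaConfig-class].
#' @export
tpcaConfig <- function(m = 50, beta = 1, gamma = 1, maxIter = 100,
                       tol = 1e-6, eps = 1e-8,
                       reconstructionNorm = c("l21", "frobenius"), seed = 0) {
  new("TpcaConfig", m = as.integer(m), beta = beta, gamma = gamma,
      maxIter = as.integer(maxIter), tol = tol, eps = eps,
      reconstructionNorm = match.arg(reconstructionNorm),
      seed = as.integer(seed))
}

#' Result of the topological PCA solver
#'
#' @slot U M x m gene loadings.
#' @slot Q N x m column-orthonormal spot embedding.
#' @slot objectiveTrace per-iteration objective values (non-increasing).
#' @slot converged whether the relative-change tolerance was met.
#' @slot nIter iterations run.
#' @slot zeta scale combination used for the regularizer (may be empty).
#' @export
setClass("TpcaResult",
  representation(U = "matrix", Q = "matrix", objectiveTrace = "numeric",
                 converged = "logical", nIter = "integer", zeta = "numeric"))

setValidity("TpcaResult", function(object) {
  QtQ <- crossprod(object@Q)
  if (max(abs(QtQ - diag(ncol(object@Q)))) > 1e-8)
    return("Q must be column-orthonormal")
  tr <- object@objectiveTrace
  if (length(tr) > 1 && any(diff(tr) > 1e-9))
    return("objectiveTrace must be non-increasing")
  TRUE
})

#' Spatially informed spot embedding
#'
#' Either loaded from an external file (the output of a spatially resolved
#' deep-learning encoder) or produced by the package's simple baseline
#' spatial encoder.
#'
#' @slot spotIds spot identifiers aligned to the expression matrix.
#' @slot Z N x d numeric embedding.
#' @slot source `"external_file"` or `"baseline_encoder"`.
#' @export
setClass("SpatialEmbedding",
  representation(spotIds = "character", Z = "matrix", source = "character"))

setValidity("SpatialEmbedding", function(object) {
  if (nrow(object@Z) != length(object@spotIds))
    return("Z rows must match spotIds")
  if (any(!is.finite(object@Z))) return("non-finite values in embedding")
  if (!object@source %in% c("external_file", "baseline_encoder"))
    return("source must be 'external_file' or 'baseline_encoder'")
  TRUE
})

#' CCA-aligned multi-view features for one scale combination
#'
#' @slot zeta the scale combination the expression-view embedding used.
#' @slot features N x (2c) matrix: spatial-view canonical scores followed by
#'   expression-view canonical scores.
#' @slot lambdas length-c non-increasing, non-negative canonical values;
#'   squared canonical correlations in \[0, 1\] under the default whitened
#'   alignment (raw squared singular values in literal mode).
#' @export
setClass("AlignedEmbedding",
  representation(zeta = "numeric", features = "matrix", lambdas = "numeric"))

setValidity("AlignedEmbedding", function(object) {
  l <- object@lambdas
  if (length(l) > 1 && any(diff(l) > 1e-10)) return("lambdas must be non-increasing")
  if (length(l) && min(l) < -1e-8) return("lambdas must be non-negative")
  if (ncol(object@features) != 2L * length(l))
    return("features must have 2c columns")
  TRUE
})

#' Cluster labels over spots
#'
#' Labels are stored zero-based, in \[0, nClasses); every class is non-empty.
#'
#' @slot spotIds spot identifiers.
#' @slot labels integer vector of labels.
#' @export
setClass("ClusterLabels",
  representation(spotIds = "character", labels = "integer"))

setValidity("ClusterLabels", function(object) {
  if (length(object@labels) != length(object@spotIds))
    return("labels length must match spotIds")
  if (length(object@labels)) {
    u <- sort(unique(object@labels))
    if (u[1] != 0L || !identical(u, seq_len(length(u)) - 1L))
      return("labels must be 0..(nClasses-1) with every class non-empty")
  }
  TRUE
})

#' @rdname ClusterLabels-class
#' @param spotIds,labels see slots; labels are recoded to 0-based order of
#'   first appearance.
#' @export
ClusterLabels <- function(spotIds, labels) {
  labels <- as.integer(factor(labels, levels = unique(labels))) - 1L
  new("ClusterLabels", spotIds = as.character(spotIds), labels = labels)
}

#' Co-association matrix of an ensemble of clusterings
#'
#' `C[i,j]` is the fraction of member label sets assigning spots i and j to
#' the same cluster; symmetric, unit diagonal, entries in \[0, 1\].
#'
#' @slot C N x N numeric matrix.
#' @export
setClass("CoAssociation", representation(Cmat = "matrix"))

setValidity("CoAssociation", function(object) {
  C <- object@Cmat
  if (nrow(C) != ncol(C)) return("C must be square")
  if (max(abs(C - t(C))) > 1e-12) return("C must be symmetric")
  if (any(diag(C) != 1)) return("diagonal of C must be exactly 1")
  if (min(C) < 0 || max(C) > 1) return("entries of C must lie in [0, 1]")
  TRUE
})

#' Residue-similarity report for a labelled embedding
#'
#' @slot rsi overall residue-similarity index in \[0, 1\].
#' @slot residue per-spot normalized between-class residue scores.
#' @slot similarity per-spot within-class similarity scores.
#' @export
setClass("RsiReport",
  representation(rsi = "numeric", residue = "numeric", similarity = "numeric"))

#' Consensus spatial-domain result
#'
#' @slot domains final [ClusterLabels-class] spatial domains.
#' @slot memberLabelsets list of per-scale-combination [ClusterLabels-class].
#' @slot coAssociation [CoAssociation-class] (ensemble mode) or NULL.
#' @slot selectedEmbedding index of the RSI-selected embedding (rsi_select
#'   mode) or NA.
#' @slot rsiValues per-member RSI values (rsi_select mode) or empty.
#' @slot config echo of the run configuration.
#' @export
setClass("ConsensusResult",
  representation(domains = "ClusterLabels", memberLabelsets = "list",
                 coAssociation = "ANY", selectedEmbedding = "integer",
                 rsiValues = "numeric", config = "list"))

#' Configuration of the synthetic layered-tissue generator
#'
#' Defaults are the package's reference simulation: a 20 x 75 spot lattice cut
#' into 5 horizontal strip domains (layered cortex-like tissue), 300 genes of
#' which 40 per domain are markers at log2 fold change 1.5, log-normal
#' baseline means, negative-binomial counts (variance mu + mu^2/theta) and
#' independent dropout.
#'
#' @slot grid integer c(rows, cols) of the spot lattice.
#' @slot layout `"strips"` (horizontal bands) or `"voronoi"`.
#' @slot nDomains number of planted domains.
#' @slot nGenes total gene count.
#' @slot nMarkersPerDomain markers per domain (disjoint across domains).
#' @slot markerLog2fc in-domain marker log2 fold change.
#' @slot baselineMeanLog c(meanlog, sdlog) of log-normal baseline gene means.
#' @slot nbDispersion negative-binomial dispersion theta.
#' @slot dropoutRate independent zeroing probability in \[0, 1).
#' @slot seed integer seed.
#' @export
setClass("SynthConfig",
  representation(grid = "integer", layout = "character", nDomains = "integer",
                 nGenes = "integer", nMarkersPerDomain = "integer",
                 markerLog2fc = "numeric", baselineMeanLog = "numeric",
                 nbDispersion = "numeric", dropoutRate = "numeric",
                 seed = "integer"))

setValidity("SynthConfig", function(object) {
  if (length(object@grid) != 2L || any(object@grid < 1L))
    return("grid must be two positive integers")
  if (!object@layout %in% c("strips", "voronoi"))
    return("layout must be 'strips' or 'voronoi'")
  if (object@nDomains < 1L || object@nGenes < 1L || object@nMarkersPerDomain < 0L)
    return("counts must be positive")
  if (object@nDomains * object@nMarkersPerDomain > object@nGenes)
    return("nDomains * nMarkersPerDomain must not exceed nGenes")
  if (object@markerLog2fc < 0) return("markerLog2fc must be >= 0")
  if (object@nbDispersion <= 0) return("nbDispersion must be positive")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    return("dropoutRate must lie in [0, 1)")
  TRUE
})

#' Construct a SynthConfig
#'
#' @param grid,layout,nDomains,nGenes,nMarkersPerDomain,markerLog2fc,baselineMeanLog,nbDispersion,dropoutRate,seed
#'   see [SynthConfig-class] slots; defaults are the layered-tissue reference
#'   simulation.
#' @return A [SynthConfig-class].
#' @export
synthConfig <- function(grid = c(20, 75), layout = c("strips", "voronoi"),
                        nDomains = 5, nGenes = 300, nMarkersPerDomain = 40,
                        markerLog2fc = 1.5, baselineMeanLog = c(log(2), 1),
                        nbDispersion = 2, dropoutRate = 0.3, seed = 0) {
  new("SynthConfig", grid = as.integer(grid), layout = match.arg(layout),
      nDomains = as.integer(nDomains), nGenes = as.integer(nGenes),
      nMarkersPerDomain = as.integer(nMarkersPerDomain),
      markerLog2fc = markerLog2fc, baselineMeanLog = as.numeric(baselineMeanLog),
      nbDispersion = nbDispersion, dropoutRate = dropoutRate,
      seed = as.integer(seed))
}

#' Synthetic spatial transcriptomics dataset with planted domains
#'
#' @slot expression raw-count [ExpressionMatrix-class].
#' @slot coords [SpatialCoords-class] on the configured lattice.
#' @slot truth planted [ClusterLabels-class].
#' @slot markerIndex named list mapping domain -> marker gene ids.
#' @export
setClass("SynthDataset",
  representation(expression = "ExpressionMatrix", coords = "SpatialCoords",
                 truth = "ClusterLabels", markerIndex = "list"))
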