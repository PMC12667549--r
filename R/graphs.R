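.expr_matrix_input <- function(X) {
  if (is(X, "ExpressionMatrix")) as.matrix(exprValues(X))
  else as.matrix(X)
}

# Pairwise squared Euclidean distances between spot columns of genes x spots V.
.spot_sqdist <- function(V) {
  G <- crossprod(V)                      # N x N Gram of spot profiles
  n2 <- diag(G)
  D2 <- outer(n2, n2, "+") - 2 * G
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  D2
}

# Neighbour orderings: for each spot, all other spots sorted by (distance,
# index). Prefixes of these rows give the k-nearest sets for every k, which
# is what makes the filtration nested by construction.
.neighbour_order <- function(D2) {
  n <- nrow(D2)
  t(vapply(seq_len(n), function(i) {
    o <- order(D2[i, ], seq_len(n))      # ties: lower spot index wins
    o[o != i][seq_len(n - 1L)]
  }, integer(n - 1L)))
}

.edges_from_prefix <- function(ord, k) {
  n <- nrow(ord)
  i <- rep(seq_len(n), each = k)
  j <- as.vector(t(ord[, seq_len(k), drop = FALSE]))
  a <- pmin(i, j); b <- pmax(i, j)
  e <- unique(cbind(a, b))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Build the expression-space kNN graph
#'
#' Distances are Euclidean between spot expression profiles (columns). The
#' edge set is union-symmetrized: (i, j) is an edge iff j is among the k
#' nearest neighbours of i or vice versa. Exact distance ties break toward
#' the lower spot index, deterministically.
#'
#' @param X an [ExpressionMatrix-class] (ideally log-transformed / HVG
#'   subset) or a plain genes x spots matrix.
#' @param k neighbour count, `1 <= k <= N-1`.
#' @param metric distance metric (only `"euclidean"`).
#' @return A [KnnGraph-class].
#' @export
knnEdges <- function(X, k, metric = "euclidean") {
  metric <- match.arg(metric, "euclidean")
  V <- .expr_matrix_input(X)
  n <- ncol(V)
  if (k < 1 || k >= n) stop(sprintf("k must satisfy 1 <= k <= N-1 (N=%d)", n))
  ord <- .neighbour_order(.spot_sqdist(V))
  new("KnnGraph", n = as.integer(n), k = as.integer(k), metric = metric,
      edges = .edges_from_prefix(ord, as.integer(k)))
}

#' Gaussian edge weights on a kNN graph
#'
#' `W[i,j] = exp(-||x_i - x_j||^2 / eta)` on edges of `g`, 0 otherwise.
#' `eta = "auto"` uses the median of squared edge distances (the median
#' heuristic).
#'
#' @param g a [KnnGraph-class] built from the same expression matrix.
#' @param X the expression matrix `g` was built from.
#' @param eta positive kernel width, or `"auto"`.
#' @return A [WeightedAdjacency-class].
#' @export
gaussianAffinity <- function(g, X, eta = "auto") {
  stopifnot(is(g, "KnnGraph"))
  V <- .expr_matrix_input(X)
  if (ncol(V) != g@n) stop("expression matrix does not match graph size")
  e <- g@edges
  d2 <- colSums((V[, e[, 1], drop = FALSE] - V[, e[, 2], drop = FALSE])^2)
  if (identical(eta, "auto")) {
    eta <- stats::median(d2)
    if (eta <= 0) eta <- 1   # degenerate duplicate-heavy input
  }
  if (!is.numeric(eta) || eta <= 0) stop("eta must be positive")
  w <- exp(-d2 / eta)
  W <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = c(w, w), dims = c(g@n, g@n), symmetric = FALSE)
  new("WeightedAdjacency", n = g@n, eta = eta, W = W)
}

#' Graph Laplacian L = D - W
#'
#' @param W a [WeightedAdjacency-class] (or symmetric adjacency matrix).
#' @return A [GraphLaplacian-class].
#' @export
graphLaplacian <- function(W) {
  A <- if (is(W, "WeightedAdjacency")) W@W else W
  if (max(abs(A - Matrix::t(A))) > 1e-12) stop("adjacency must be symmetric")
  n <- nrow(A)
  L <- Matrix::Diagonal(n, Matrix::rowSums(A)) - A
  new("GraphLaplacian", n = as.integer(n), L = L)
}

.unweighted_laplacian <- function(edges, n) {
  if (nrow(edges) == 0L)
    return(new("GraphLaplacian", n = as.integer(n),
               L = Matrix::sparseMatrix(i = integer(), j = integer(),
                                        x = numeric(), dims = c(n, n))))
  A <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                            j = c(edges[, 2], edges[, 1]),
                            x = 1, dims = c(n, n))
  new("GraphLaplacian", n = as.integer(n),
      L = Matrix::Diagonal(n, Matrix::rowSums(A)) - A)
}

#' kNN-induced filtration of persistent Laplacians
#'
#' For each neighbour count k in the strictly decreasing list `ks`, builds
#' the unweighted graph Laplacian of the union-symmetrized kNN graph:
#' off-diagonal entries are -1 on edges and the diagonal holds node degrees.
#' Because all snapshots share one neighbour ordering (same metric, same
#' lower-index tie rule), the edge set at a smaller k is nested inside that
#' at any larger k, and the zero-eigenvalue multiplicity of each snapshot
#' counts its connected components (the Betti-0 number at that scale).
#'
#' The printed per-scale Laplacian condition (`-1` iff `x_j` is a k-nearest
#' neighbour of `x_i`) is asymmetric as stated; edges are union-symmetrized
#' here so every snapshot is a genuine symmetric PSD Laplacian, consistent
#' with the method's own edge-set definition.
#'
#' @param X expression matrix (see [knnEdges()]).
#' @param ks strictly decreasing integer scales (default `c(15, 12, 9, 6)`).
#' @param weighted use Gaussian edge weights ([gaussianAffinity()] with the
#'   median heuristic) instead of unit weights. Default FALSE.
#' @return A [LaplacianFiltration-class].
#' @export
knnFiltration <- function(X, ks = c(15, 12, 9, 6), weighted = FALSE) {
  ks <- as.integer(ks)
  if (length(ks) > 1 && any(diff(ks) >= 0)) stop("ks must be strictly decreasing")
  V <- .expr_matrix_input(X)
  n <- ncol(V)
  if (max(ks) >= n) stop(sprintf("max(ks)=%d must be < N=%d", max(ks), n))
  if (min(ks) < 1) stop("ks must be positive")
  ord <- .neighbour_order(.spot_sqdist(V))
  laps <- lapply(ks, function(k) {
    e <- .edges_from_prefix(ord, k)
    if (weighted) {
      g <- new("KnnGraph", n = as.integer(n), k = k, metric = "euclidean",
               edges = e)
      graphLaplacian(gaussianAffinity(g, V))
    } else {
      .unweighted_laplacian(e, n)
    }
  })
  new("LaplacianFiltration", ks = ks, laplacians = laps, n = as.integer(n))
}

#' Accumulate filtration Laplacians into L_P
#'
#' `L_P = sum_k zeta_k L^k`; the weights select which connectivity scales
#' are "switched on". Being a sum of PSD Laplacians with non-negative
#' weights, L_P is PSD with zero row sums.
#'
#' @param f a [LaplacianFiltration-class].
#' @param zeta weight per scale; by default restricted to 0/1, real
#'   non-negative weights allowed with `allowReal = TRUE`. Not all zero.
#' @param allowReal permit non-binary weights.
#' @return An [AccumulatedLaplacian-class].
#' @export
accumulateLaplacians <- function(f, zeta, allowReal = FALSE) {
  stopifnot(is(f, "LaplacianFiltration"))
  if (length(zeta) != length(f@ks))
    stop("zeta length must equal the number of filtration scales")
  if (all(zeta == 0)) stop("empty scale combination")
  if (!allowReal && !all(zeta %in% c(0, 1)))
    stop("zeta must be binary (use allowReal=TRUE for real weights)")
  LP <- Reduce(`+`, Map(function(z, gl) z * gl@L, zeta, f@laplacians))
  new("AccumulatedLaplacian", zeta = as.numeric(zeta), ks = f@ks, LP = LP)
}

#' Enumerate the binary scale-combination grid
#'
#' All `2^p - 1` non-zero on/off vectors over p filtration scales, in binary
#' counting order with the most significant bit on the first (largest-k)
#' scale: for p = 2 the order is (0,1), (1,0), (1,1).
#'
#' @param p number of scales, >= 1.
#' @return A list of 0/1 numeric vectors.
#' @export
zetaGrid <- function(p) {
  p <- as.integer(p)
  if (p < 1L) stop("p must be >= 1")
  lapply(seq_len(2^p - 1L), function(i)
    as.numeric(rev(as.integer(intToBits(i))[seq_len(p)])))
}

#' Export a graph as an edge-list TSV
#'
#' @param g a [KnnGraph-class] or [WeightedAdjacency-class].
#' @param path output TSV (columns i, j, weight).
#' @export
writeEdgeList <- function(g, path) {
  if (is(g, "KnnGraph")) {
    df <- data.frame(i = g@edges[, 1], j = g@edges[, 2], weight = 1)
  } else if (is(g, "WeightedAdjacency")) {
    W <- methods::as(methods::as(g@W, "generalMatrix"), "TsparseMatrix")
    keep <- W@i < W@j
    df <- data.frame(i = W@i[keep] + 1L, j = W@j[keep] + 1L, weight = W@x[keep])
    df <- df[order(df$i, df$j), ]
  } else stop("unsupported graph type")
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
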