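#' Baseline spatial encoder
#'
#' A deliberately simple, deterministic stand-in for spatially resolved
#' deep-learning encoders: builds a union-symmetrized kNN graph on the spot
#' coordinates, applies `rounds` of neighbour-mean smoothing (each spot
#' averaged with its spatial neighbours) to the expression profiles, and
#' projects the smoothed spots onto their top principal components. With
#' `rounds = 0` it is plain expression PCA.
#'
#' @param X an [ExpressionMatrix-class] (log scale recommended).
#' @param coords a [SpatialCoords-class] aligned to `X`.
#' @param kSpatial spatial neighbour count (default 6, a hex/grid-like
#'   neighbourhood).
#' @param rounds smoothing rounds (default 2).
#' @param nComp number of principal components (default 30).
#' @param seed integer seed (the computation is deterministic; the seed is
#'   consumed for interface stability).
#' @return A [SpatialEmbedding-class] with source `"baseline_encoder"`.
#' @export
baselineSpatialEmbedding <- function(X, coords, kSpatial = 6, rounds = 2,
                                     nComp = 30, seed = 0) {
  stopifnot(is(X, "ExpressionMatrix"), is(coords, "SpatialCoords"))
  if (!identical(spotIds(X), spotIds(coords)))
    stop("coords spot ids do not match expression spot ids")
  V <- as.matrix(exprValues(X))
  n <- ncol(V)
  if (kSpatial >= n) stop("kSpatial must be < number of spots")
  set.seed(seed)
  if (rounds > 0) {
    g <- knnEdges(t(coordsXY(coords)), k = kSpatial)
    e <- graphEdges(g)
    A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2], seq_len(n)),
                              j = c(e[, 2], e[, 1], seq_len(n)),
                              x = 1, dims = c(n, n))
    A <- A %*% Matrix::Diagonal(n, 1 / Matrix::colSums(A))
    for (r in seq_len(rounds)) V <- as.matrix(V %*% A)
  }
  nComp <- min(nComp, n - 1L, nrow(V))
  pc <- prcomp(t(V), center = TRUE, scale. = FALSE, rank. = nComp)
  Z <- .sign_fix(pc$x[, seq_len(nComp), drop = FALSE])
  new("SpatialEmbedding", spotIds = spotIds(X), Z = unname(Z),
      source = "baseline_encoder")
}

#' Load an externally computed spatial embedding
#'
#' Reads a TSV/CSV with a spot-id column (first column, or one named
#' `spot_id`) followed by numeric embedding columns, and reorders rows to
#' the canonical spot order. Missing or extra spots are a hard error.
#'
#' @param path file path.
#' @param spotIds canonical spot order to match.
#' @return A [SpatialEmbedding-class] with source `"external_file"`.
#' @export
loadEmbedding <- function(path, spotIds) {
  df <- data.table::fread(path, data.table = FALSE, check.names = FALSE)
  idCol <- if ("spot_id" %in% colnames(df)) "spot_id" else colnames(df)[1]
  ids <- as.character(df[[idCol]])
  body <- df[, setdiff(colnames(df), idCol), drop = FALSE]
  for (j in seq_along(body))
    if (!is.numeric(body[[j]]))
      stop(sprintf("non-numeric embedding column '%s'", colnames(body)[j]))
  missing <- setdiff(spotIds, ids)
  extra <- setdiff(ids, spotIds)
  if (length(missing))
    stop(sprintf("embedding file is missing spots: %s",
                 paste(missing, collapse = ", ")))
  if (length(extra))
    stop(sprintf("embedding file has unknown spots: %s",
                 paste(extra, collapse = ", ")))
  Z <- as.matrix(body)[match(spotIds, ids), , drop = FALSE]
  new("SpatialEmbedding", spotIds = as.character(spotIds), Z = unname(Z),
      source = "external_file")
}

#' Write an embedding as TSV
#'
#' @param x a [SpatialEmbedding-class], [TpcaResult-class] or matrix.
#' @param path output path.
#' @param spotIds spot ids (required when `x` is a bare matrix or
#'   [TpcaResult-class]).
#' @export
writeEmbedding <- function(x, path, spotIds = NULL) {
  if (is(x, "SpatialEmbedding")) {
    Z <- embedding(x); ids <- spotIds(x)
  } else if (is(x, "TpcaResult")) {
    Z <- embedding(x); ids <- spotIds
  } else {
    Z <- as.matrix(x); ids <- spotIds
  }
  if (is.null(ids)) stop("spotIds required")
  df <- data.frame(spot_id = ids, Z, check.names = FALSE)
  colnames(df) <- c("spot_id", paste0("dim", seq_len(ncol(Z))))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

.center_cols <- function(M) sweep(M, 2, colMeans(M), "-")

# Orthonormal basis of the column space, dropping numerically null
# directions; returns the basis and the rank.
.orth_basis <- function(M, tol = 1e-10) {
  s <- svd(M)
  r <- sum(s$d > tol * max(s$d, .Machine$double.eps))
  list(B = s$u[, seq_len(r), drop = FALSE], rank = r)
}

#' Canonical correlation alignment of a spatial and an expression embedding
#'
#' Solves the cross-product eigenproblem
#' `(Zs^T Qc)(Qc^T Zs) q = lambda q` via an SVD of `M = Zs^T Qc`: the left
#' singular vectors are the spatial-view canonical directions `q`, the right
#' singular vectors the expression-view directions `p` (the `M^T q / lambda`
#' vectors, unit-normalized), and `lambda` the squared singular values --
#' the squared canonical correlations, sorted in descending order. The
#' aligned feature matrix concatenates both views' canonical scores,
#' `F = [Zs q_1..q_c | Qc p_1..p_c]`.
#'
#' By default each view is column-centered and its column space
#' orthonormalized before the cross-product (classical CCA), which is what
#' makes `lambda` a squared correlation bounded by 1. `whiten = FALSE`
#' applies the cross-product to the centered views rescaled only to unit
#' spectral norm (a PLS-like variant; the lambdas then measure shared
#' variance rather than squared correlation).
#'
#' @param Zs a [SpatialEmbedding-class] (or N x d matrix).
#' @param Qc N x m expression-view embedding ([TpcaResult-class] or matrix).
#' @param c number of canonical pairs, or `"auto"` (all lambda > 1e-10).
#' Each canonical score column is scaled by its canonical correlation
#' `sqrt(lambda_i)` (disable with `weightScores = FALSE`), so that pairs
#' carrying more shared signal dominate downstream distances instead of
#' every canonical variate entering at identical unit scale.
#'
#' @param center column-center both views first (default TRUE).
#' @param whiten orthonormalize each view's column space first (default
#'   TRUE; see Details).
#' @param weightScores scale score columns by `sqrt(lambda)` (default TRUE).
#' @param zeta scale-combination tag carried through to the result.
#' @return An [AlignedEmbedding-class].
#' @export
ccaAlign <- function(Zs, Qc, c = "auto", center = TRUE, whiten = TRUE,
                     weightScores = TRUE, zeta = numeric(0)) {
  Z <- if (is(Zs, "SpatialEmbedding")) embedding(Zs) else as.matrix(Zs)
  if (is(Qc, "TpcaResult")) {
    if (!length(zeta)) zeta <- Qc@zeta
    Qc <- embedding(Qc)
  }
  Qm <- as.matrix(Qc)
  if (nrow(Z) != nrow(Qm)) stop("views must have the same number of spots")
  if (center) { Z <- .center_cols(Z); Qm <- .center_cols(Qm) }
  if (whiten) {
    bz <- .orth_basis(Z); bq <- .orth_basis(Qm)
    Zv <- bz$B; Qv <- bq$B
  } else {
    # literal cross-product mode: the printed eigenproblem applied to the
    # (centered) views as-is; lambdas are then raw squared singular values
    # and carry the views' scale
    Zv <- Z
    Qv <- Qm
  }
  M <- crossprod(Zv, Qv)
  s <- svd(M)
  lambda <- s$d^2
  cmax <- min(ncol(Zv), ncol(Qv))
  if (identical(c, "auto")) {
    c <- sum(lambda > 1e-10)
    if (c == 0L) stop("no shared signal (rank-0 cross-product)")
  }
  c <- as.integer(c)
  if (c < 1L || c > cmax)
    stop(sprintf("c must be in 1..%d", cmax))
  qv <- s$u[, seq_len(c), drop = FALSE]
  pv <- s$v[, seq_len(c), drop = FALSE]
  Fmat <- cbind(Zv %*% qv, Qv %*% pv)
  lam <- lambda[seq_len(c)]
  if (whiten) lam <- pmin(lam, 1)   # squared correlations up to fp noise
  if (weightScores) {
    w <- sqrt(lam)
    Fmat <- Fmat * rep(c(w, w), each = nrow(Fmat))
  }
  new("AlignedEmbedding", zeta = as.numeric(zeta),
      features = .sign_fix(Fmat), lambdas = lam)
}

#' Align every scale-combination embedding with the spatial embedding
#'
#' @param Zs a [SpatialEmbedding-class].
#' @param scaleEmbeddings list of [TpcaResult-class] (from
#'   [embedAllScales()]).
#' @param ... passed to [ccaAlign()].
#' @return A list of [AlignedEmbedding-class], order preserved.
#' @export
alignAll <- function(Zs, scaleEmbeddings, ...) {
  lapply(scaleEmbeddings, function(r) ccaAlign(Zs, r, ...))
}
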