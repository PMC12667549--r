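#' @importFrom mgcv slanczos
NULL

.sign_fix <- function(Q) {
  # deterministic column sign convention: largest-magnitude entry positive
  for (j in seq_len(ncol(Q))) {
    i <- which.max(abs(Q[, j]))
    if (Q[i, j] < 0) Q[, j] <- -Q[, j]
  }
  Q
}

.row_norms <- function(M) sqrt(rowSums(M^2))

# Implicit representation of the Q-update matrix
#   A = diag(d2vec) + LPg - t(Xw) %*% Xw
# (d2vec = beta * D2 diagonal, LPg = gamma * L_P, Xw = sqrt(D1) X).
.A_matvec <- function(parts, V) {
  out <- parts$d2vec * V
  if (!is.null(parts$LPg)) out <- out + as.matrix(parts$LPg %*% V)
  out - crossprod(parts$Xw, parts$Xw %*% V)
}

.A_dense <- function(parts) {
  A <- -crossprod(parts$Xw)
  diag(A) <- diag(A) + parts$d2vec
  if (!is.null(parts$LPg)) A <- A + as.matrix(parts$LPg)
  A
}

.slanczos_smallest <- function(parts, m) {
  r <- mgcv::slanczos(.A_dense(parts), k = 0, kl = m, tol = 1e-12)
  o <- order(r$values)
  list(Q = r$vectors[, o, drop = FALSE], values = r$values[o])
}

# Smallest-m eigenvectors of A. Dense eigen below `denseThreshold`; above it,
# a warm-started augmented Rayleigh-Ritz iteration on the subspace
# [W, A W] (the start block W is contained in the search space, so the Ritz
# trace can only improve on it -- this is what keeps the IRLS objective
# monotone even before the eigenbasis is fully converged), with a Lanczos
# (mgcv::slanczos) fallback when the residual stalls. Deterministic.
.smallest_eigvecs <- function(parts, m, warmQ = NULL, denseThreshold = 800,
                              tolEig = 1e-6, maxSweeps = 15) {
  n <- length(parts$d2vec)
  if (n <= denseThreshold) {
    e <- eigen(.A_dense(parts), symmetric = TRUE)
    idx <- seq(n - m + 1L, n)
    return(list(Q = e$vectors[, rev(idx), drop = FALSE],
                values = e$values[rev(idx)]))
  }
  if (is.null(warmQ)) return(.slanczos_smallest(parts, m))
  W <- warmQ
  prevTrace <- Inf
  for (sweep in seq_len(maxSweeps)) {
    AW <- .A_matvec(parts, W)
    # augment only with residual directions that are not yet converged;
    # A W is reused for the W block of the basis, so each sweep pays one
    # m-column matvec plus one matvec over the active residual columns
    WtAW <- crossprod(W, AW)
    Rblk <- AW - W %*% WtAW
    scaleEst <- max(sqrt(colSums(AW^2)), 1)
    act <- sqrt(colSums(Rblk^2)) > tolEig * scaleEst
    if (any(act)) {
      Rs <- Rblk[, act, drop = FALSE]
      Rs <- Rs - W %*% crossprod(W, Rs)          # re-orthogonalize (fp)
      qrR <- qr(Rs)
      keep <- abs(diag(qr.R(qrR))) > 1e-10 * scaleEst
      Rq <- qr.Q(qrR)[, keep, drop = FALSE]
    } else {
      Rq <- matrix(0, n, 0)
    }
    if (ncol(Rq)) {
      ARq <- .A_matvec(parts, Rq)
      B <- cbind(W, Rq)
      AB <- cbind(AW, ARq)
      Tm <- crossprod(B, AB)
    } else {
      B <- W; AB <- AW; Tm <- WtAW
    }
    Tm <- (Tm + t(Tm)) / 2
    e <- eigen(Tm, symmetric = TRUE)
    sel <- rev(seq(ncol(Tm) - m + 1L, ncol(Tm)))
    Y <- e$vectors[, sel, drop = FALSE]
    Q <- B %*% Y
    vals <- e$values[sel]
    res <- AB %*% Y - Q * rep(vals, each = n)   # A Q - Q diag(vals), free
    if (max(sqrt(colSums(res^2))) < tolEig * max(abs(vals), 1))
      return(list(Q = Q, values = vals))
    # the IRLS step only needs the minimizing trace; once it has stopped
    # improving, further eigenvector polishing is wasted work
    tr <- sum(vals)
    if (abs(prevTrace - tr) <= max(tolEig * 1e-4, 1e-15) * max(1, abs(tr)))
      return(list(Q = Q, values = vals))
    prevTrace <- tr
    W <- Q
  }
  list(Q = Q, values = vals)
}

.objective_terms <- function(V, U, Q, LPmat, beta, gamma, norm, R = NULL) {
  if (is.null(R)) R <- V - tcrossprod(U, Q)
  recon <- if (norm == "l21") sum(.row_norms(R)) else sum(R^2)
  sparsity <- if (beta > 0) beta * sum(.row_norms(Q)) else 0
  topo <- if (gamma > 0 && !is.null(LPmat))
    gamma * sum(Q * as.matrix(LPmat %*% Q)) else 0
  recon + sparsity + topo
}

.lp_matrix <- function(LP) {
  if (is.null(LP)) NULL
  else if (is(LP, "AccumulatedLaplacian")) LP@LP
  else if (is(LP, "GraphLaplacian")) LP@L
  else LP
}

#' Topological PCA objective
#'
#' Evaluates `||X - U Q^T||_{2,1} + beta ||Q||_{2,1} + gamma Tr(Q^T L_P Q)`
#' where the L2,1 norm sums Euclidean row norms. In `"frobenius"` mode the
#' first term is the squared Frobenius norm instead.
#'
#' @param X [ExpressionMatrix-class] or genes x spots matrix.
#' @param U M x m loadings.
#' @param Q N x m column-orthonormal spot embedding.
#' @param LP [AccumulatedLaplacian-class], [GraphLaplacian-class], matrix or
#'   NULL.
#' @param beta,gamma non-negative weights.
#' @param reconstructionNorm `"l21"` (default) or `"frobenius"`.
#' @return The objective value (non-negative scalar).
#' @export
tpcaObjective <- function(X, U, Q, LP = NULL, beta = 1, gamma = 1,
                          reconstructionNorm = c("l21", "frobenius")) {
  reconstructionNorm <- match.arg(reconstructionNorm)
  V <- .expr_matrix_input(X)
  if (max(abs(crossprod(Q) - diag(ncol(Q)))) > 1e-6)
    stop("Q is not column-orthonormal")
  .objective_terms(V, U, Q, .lp_matrix(LP), beta, gamma, reconstructionNorm)
}

#' Solve topological PCA by alternating IRLS
#'
#' Minimizes the [tpcaObjective()] under the orthonormality constraint
#' `Q^T Q = I` by iteratively reweighted alternating minimization. Q is
#' initialized from the top-m right singular subspace of X. Each iteration
#' rebuilds the L2,1 row weights (`D1` for the reconstruction residual, `D2`
#' for Q's rows, both floored at `eps`), sets Q to the m smallest
#' eigenvectors of `beta D2 + gamma L_P - X^T D1 X`, and takes the exact
#' loading update `U = X Q`. Both steps decrease a majorant of the
#' objective, so the objective trace is non-increasing. In `"frobenius"`
#' mode `D1` is the identity (the reconstruction term is exactly quadratic)
#' and the scheme reduces to plain graph-regularized sparse PCA; with
#' `beta = gamma = 0` it reduces to PCA.
#'
#' Convergence is declared when the relative objective change drops below
#' `tol`. Column signs follow a fixed convention (largest-magnitude entry
#' positive) so results are reproducible across platforms.
#'
#' @param X [ExpressionMatrix-class] (log-transformed or HVG subset) or a
#'   genes x spots matrix.
#' @param LP accumulated Laplacian regularizer (or NULL for plain sparse
#'   PCA).
#' @param cfg a [TpcaConfig-class].
#' @param initQ optional N x m warm-start embedding (used internally to
#'   share the SVD initialization across scale combinations).
#' @return A [TpcaResult-class].
#' @export
solveTpca <- function(X, LP = NULL, cfg = tpcaConfig(), initQ = NULL) {
  V <- .expr_matrix_input(X)
  if (any(!is.finite(V))) stop("non-finite values in X")
  M <- nrow(V); N <- ncol(V); m <- cfg@m
  if (m > min(M, N)) stop(sprintf("m=%d exceeds min(M, N)=%d", m, min(M, N)))
  LPmat <- .lp_matrix(LP)
  if (!is.null(LPmat) && nrow(LPmat) != N)
    stop("L_P dimension does not match spot count")
  set.seed(cfg@seed)
  norm <- cfg@reconstructionNorm
  beta <- cfg@beta; gamma <- cfg@gamma
  LPg <- if (gamma > 0 && !is.null(LPmat)) gamma * LPmat else NULL

  Q <- if (is.null(initQ)) svd(V, nu = 0, nv = m)$v else initQ
  Q <- .sign_fix(Q)
  U <- V %*% Q
  Rres <- V - tcrossprod(U, Q)
  trace <- .objective_terms(V, U, Q, LPmat, beta, gamma, norm, R = Rres)
  converged <- FALSE
  it <- 0L
  warm <- NULL
  for (it in seq_len(cfg@maxIter)) {
    d1 <- if (norm == "l21") 1 / (2 * pmax(.row_norms(Rres), cfg@eps))
          else rep.int(1, M)
    d2 <- if (beta > 0) beta / (2 * pmax(.row_norms(Q), cfg@eps))
          else rep.int(0, N)
    parts <- list(d2vec = d2, LPg = LPg, Xw = sqrt(d1) * V)
    es <- .smallest_eigvecs(parts, m, warmQ = if (is.null(warm)) Q else warm)
    Q <- es$Q
    warm <- Q
    U <- V %*% Q
    Rres <- V - tcrossprod(U, Q)
    obj <- .objective_terms(V, U, Q, LPmat, beta, gamma, norm, R = Rres)
    prev <- trace[length(trace)]
    trace <- c(trace, obj)
    if (abs(prev - obj) <= cfg@tol * max(abs(prev), 1e-12)) {
      converged <- TRUE
      break
    }
  }
  Q <- .sign_fix(Q)       # final deterministic sign convention
  U <- V %*% Q
  new("TpcaResult", U = U, Q = Q, objectiveTrace = trace,
      converged = converged, nIter = it,
      zeta = if (is(LP, "AccumulatedLaplacian")) LP@zeta else numeric(0))
}

#' Embed all scale combinations
#'
#' Runs [solveTpca()] once per non-zero binary combination of the filtration
#' scales (see [zetaGrid()]), with identical configuration and seed; the SVD
#' initialization is computed once and shared, so each combination's result
#' is identical to a direct [solveTpca()] call with that accumulated
#' Laplacian.
#'
#' @param X expression matrix (see [solveTpca()]).
#' @param filtration a [LaplacianFiltration-class].
#' @param cfg a [TpcaConfig-class].
#' @return A list of [TpcaResult-class], ordered as [zetaGrid()].
#' @export
embedAllScales <- function(X, filtration, cfg = tpcaConfig()) {
  stopifnot(is(filtration, "LaplacianFiltration"))
  V <- .expr_matrix_input(X)
  set.seed(cfg@seed)
  initQ <- .sign_fix(svd(V, nu = 0, nv = cfg@m)$v)
  lapply(zetaGrid(length(filtration@ks)), function(z) {
    solveTpca(V, accumulateLaplacians(filtration, z), cfg, initQ = initQ)
  })
}
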