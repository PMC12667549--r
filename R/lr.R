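#' Ligand-receptor edge enrichment across graph views
#'
#' For each graph view G and ligand-receptor pair (l, r), the observed score
#' is the mean symmetric edge product of log-expression,
#' `1/|E| * sum over edges (i,j) of (x_l,i * x_r,j + x_l,j * x_r,i) / 2`.
#' The null distribution comes from `nPerm` seeded random permutations of
#' the spot-to-profile assignment (the graph is held fixed and whole
#' expression columns are shuffled, preserving within-spot gene-gene
#' correlation); the z-score standardizes the observed score against the
#' permutation mean and sd. A permutation-invariant (constant) score has
#' null sd 0 and is reported as z = 0 with `degenerate = TRUE`.
#'
#' @param graphs named list of [KnnGraph-class] over the same spots
#'   (e.g. the spatial graph and the expression graphs at each scale).
#' @param X an [ExpressionMatrix-class] (log scale) containing the genes.
#' @param pairs data.frame with columns `ligand` and `receptor`.
#' @param nPerm number of permutations (>= 100; default 1000).
#' @param seed integer seed.
#' @param allowSelfPairs permit ligand == receptor rows.
#' @return A data.frame with columns graph_tag, ligand, receptor,
#'   observed_score, null_mean, null_sd, z, degenerate.
#' @export
lrEdgeEnrichment <- function(graphs, X, pairs, nPerm = 1000, seed = 0,
                             allowSelfPairs = FALSE) {
  stopifnot(is(X, "ExpressionMatrix"), is.list(graphs))
  if (is.null(names(graphs)) || any(names(graphs) == ""))
    names(graphs) <- paste0("graph", seq_along(graphs))
  if (nPerm < 100) stop("nPerm must be >= 100")
  pairs <- as.data.frame(pairs)
  if (!all(c("ligand", "receptor") %in% colnames(pairs)))
    stop("pairs must have columns 'ligand' and 'receptor'")
  if (!allowSelfPairs && any(pairs$ligand == pairs$receptor))
    stop("ligand == receptor pairs present (set allowSelfPairs=TRUE)")
  gene2row <- match(c(pairs$ligand, pairs$receptor), geneIds(X))
  if (any(is.na(gene2row))) {
    bad <- unique(c(pairs$ligand, pairs$receptor)[is.na(gene2row)])
    stop(sprintf("gene(s) absent from expression matrix: %s",
                 paste(bad, collapse = ", ")))
  }
  V <- as.matrix(exprValues(X))
  n <- ncol(V)
  set.seed(seed)
  perms <- lapply(seq_len(nPerm), function(p) sample.int(n))

  score <- function(a, b, i, j) mean((a[i] * b[j] + a[j] * b[i]) / 2)

  out <- list()
  for (gname in names(graphs)) {
    g <- graphs[[gname]]
    stopifnot(is(g, "KnnGraph"))
    if (g@n != n) stop("graph spot count does not match expression matrix")
    e <- graphEdges(g)
    if (nrow(e) == 0L) stop(sprintf("graph '%s' has no edges", gname))
    i <- e[, 1]; j <- e[, 2]
    for (r in seq_len(nrow(pairs))) {
      a <- V[match(pairs$ligand[r], geneIds(X)), ]
      b <- V[match(pairs$receptor[r], geneIds(X)), ]
      obs <- score(a, b, i, j)
      null <- vapply(perms, function(p) score(a[p], b[p], i, j), numeric(1))
      mu <- mean(null); sdv <- stats::sd(null)
      degenerate <- sdv == 0
      out[[length(out) + 1L]] <- data.frame(
        graph_tag = gname, ligand = pairs$ligand[r],
        receptor = pairs$receptor[r], observed_score = obs,
        null_mean = mu, null_sd = sdv,
        z = if (degenerate) 0 else (obs - mu) / sdv,
        degenerate = degenerate)
    }
  }
  do.call(rbind, out)
}
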