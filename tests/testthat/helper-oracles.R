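# Independent oracles used across tests. These deliberately re-derive results
# by brute force / enumeration, not by calling the code paths they check.

# all-pairs kNN edges by direct distance enumeration
bf_knn_edges <- function(V, k) {
  n <- ncol(V)
  D <- as.matrix(dist(t(V)))
  edges <- matrix(0L, 0, 2)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nb <- others[order(D[i, others], others)][seq_len(k)]
    edges <- rbind(edges, cbind(pmin(i, nb), pmax(i, nb)))
  }
  edges <- unique(edges)
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# union-find connected components from an edge list
uf_components <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_len(n), find, 1L)))
}

# pairwise co-association by explicit pair counting
bf_coassociation <- function(labelsets) {
  n <- length(labelsets[[1]])
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    C[i, j] <- mean(vapply(labelsets, function(l) l[i] == l[j], logical(1)))
  }
  diag(C) <- 1
  C
}

# zero-eigenvalue multiplicity of a symmetric PSD matrix
zero_eig_mult <- function(L, tol = 1e-8) {
  ev <- eigen(as.matrix(L), symmetric = TRUE, only.values = TRUE)$values
  sum(abs(ev) < tol * max(1, max(abs(ev))))
}

edge_key <- function(e) paste(e[, 1], e[, 2])

# random seeded expression fixture (genes x spots, log-ish scale)
rand_expr <- function(M, N, seed) {
  set.seed(seed)
  matrix(abs(rnorm(M * N)), M, N)
}
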