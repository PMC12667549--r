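#' Generate a synthetic layered-tissue spatial transcriptomics dataset
#'
#' Spots sit on a rows x cols lattice. `"strips"` layout slices the lattice
#' into `nDomains` horizontal bands (layered-cortex-like tissue);
#' `"voronoi"` assigns each spot to the nearest of `nDomains` seeded
#' centres. Baseline per-gene means are log-normal; each domain owns a
#' disjoint block of marker genes whose in-domain mean is multiplied by
#' `2^markerLog2fc`. Counts are negative-binomial with dispersion theta
#' (variance `mu + mu^2/theta`), then independently zeroed with probability
#' `dropoutRate`. Fully reproducible under the config seed.
#'
#' @param cfg a [SynthConfig-class] (see [synthConfig()] for the reference
#'   layered-tissue defaults).
#' @return A [SynthDataset-class].
#' @export
generateSynth <- function(cfg = synthConfig()) {
  stopifnot(is(cfg, "SynthConfig"))
  methods::validObject(cfg)
  set.seed(cfg@seed)
  rows <- cfg@grid[1]; cols <- cfg@grid[2]
  n <- rows * cols
  xy <- cbind(x = rep(seq_len(cols), times = rows),
              y = rep(seq_len(rows), each = cols))
  ids <- sprintf("spot_%04d", seq_len(n))

  if (cfg@layout == "strips") {
    band <- pmin(floor((xy[, "y"] - 1) / (rows / cfg@nDomains)),
                 cfg@nDomains - 1)
    truth <- as.integer(band)
  } else {
    centres <- cbind(runif(cfg@nDomains, 1, cols), runif(cfg@nDomains, 1, rows))
    d2 <- outer(xy[, 1], centres[, 1], "-")^2 + outer(xy[, 2], centres[, 2], "-")^2
    truth <- max.col(-d2, ties.method = "first") - 1L
  }
  if (length(unique(truth)) != cfg@nDomains)
    stop("layout produced empty domains; enlarge the grid or reduce nDomains")

  gids <- sprintf("gene_%04d", seq_len(cfg@nGenes))
  mu0 <- rlnorm(cfg@nGenes, meanlog = cfg@baselineMeanLog[1],
                sdlog = cfg@baselineMeanLog[2])
  nMark <- cfg@nMarkersPerDomain
  markerIdx <- split(seq_len(cfg@nDomains * nMark),
                     rep(seq_len(cfg@nDomains), each = nMark))
  names(markerIdx) <- paste0("domain", seq_len(cfg@nDomains) - 1L)

  fc <- 2^cfg@markerLog2fc
  counts <- matrix(0L, cfg@nGenes, n)
  for (d in seq_len(cfg@nDomains)) {
    inDom <- truth == (d - 1L)
    mu <- mu0
    mu[markerIdx[[d]]] <- mu[markerIdx[[d]]] * fc
    counts[, inDom] <- rnbinom(cfg@nGenes * sum(inDom),
                               size = cfg@nbDispersion, mu = mu)
  }
  if (cfg@dropoutRate > 0) {
    drop <- matrix(rbinom(length(counts), 1, cfg@dropoutRate) == 1,
                   nrow(counts), ncol(counts))
    counts[drop] <- 0L
  }
  storage.mode(counts) <- "integer"
  new("SynthDataset",
      expression = ExpressionMatrix(counts, geneIds = gids, spotIds = ids,
                                    state = "raw_counts"),
      coords = SpatialCoords(ids, xy),
      truth = ClusterLabels(ids, truth),
      markerIndex = lapply(markerIdx, function(i) gids[i]))
}

#' Score recovery of planted domains
#'
#' Compares a pipeline result against the planted truth by NMI and ARI,
#' matching on spot ids (the result may cover a subset of spots, e.g. after
#' QC filtering).
#'
#' @param result a [ConsensusResult-class] or [ClusterLabels-class].
#' @param truth the planted [ClusterLabels-class].
#' @return Named numeric `c(nmi =, ari =)`.
#' @export
evaluateRecovery <- function(result, truth) {
  lab <- if (is(result, "ConsensusResult")) domains(result) else result
  stopifnot(is(lab, "ClusterLabels"), is(truth, "ClusterLabels"))
  idx <- match(spotIds(lab), spotIds(truth))
  if (any(is.na(idx)))
    stop("result contains spot ids absent from the truth labels")
  tl <- clusterLabels(truth)[idx]
  c(nmi = nmi(clusterLabels(lab), tl), ari = ari(clusterLabels(lab), tl))
}

#' Write a synthetic dataset to disk
#'
#' Writes the MTX directory, coordinates TSV and truth TSV, consumable by
#' the package's readers and command-line interface.
#'
#' @param ds a [SynthDataset-class].
#' @param dir output directory (created if needed).
#' @export
writeSynth <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeExpression(ds@expression, file.path(dir, "expression"), "mtx_dir")
  writeCoords(ds@coords, file.path(dir, "coords.tsv"))
  data.table::fwrite(data.frame(spot_id = spotIds(ds@truth),
                                domain = clusterLabels(ds@truth)),
                     file.path(dir, "truth.tsv"), sep = "\t")
  invisible(dir)
}
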