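#' @importFrom data.table fread fwrite setnames
NULL

.read_table_file <- function(path, sep) {
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                          check.names = FALSE, colClasses = list(character = 1))
  ids <- as.character(dt[[1]])
  body <- dt[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at row %d, column %d of %s",
                     col[bad[1]], bad[1], j + 1L, path))
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  m
}

.first_existing <- function(dir, names) {
  for (nm in names) {
    p <- file.path(dir, nm)
    if (file.exists(p)) return(p)
  }
  NULL
}

#' Read an expression matrix
#'
#' Reads a spot/cell-by-gene count matrix from a 10x-style MatrixMarket
#' directory (`matrix.mtx` + `features.tsv` + `barcodes.tsv`, optionally
#' gzipped) or from a dense CSV/TSV with genes as rows (header = spot ids,
#' first column = gene ids). The returned matrix is always oriented genes x
#' spots; set `spotsAsRows = TRUE` when a dense file stores spots as rows.
#'
#' @param path directory (`mtx_dir`) or file (`csv`/`tsv`).
#' @param format one of `"mtx_dir"`, `"csv"`, `"tsv"`.
#' @param spotsAsRows transpose a dense input on load.
#' @return An [ExpressionMatrix-class] with state `"raw_counts"`.
#' @export
readExpression <- function(path, format = c("mtx_dir", "csv", "tsv"),
                           spotsAsRows = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("path does not exist: %s", path))
  if (format == "mtx_dir") {
    mtx <- .first_existing(path, c("matrix.mtx", "matrix.mtx.gz"))
    fts <- .first_existing(path, c("features.tsv", "features.tsv.gz",
                                   "genes.tsv", "genes.tsv.gz"))
    bcs <- .first_existing(path, c("barcodes.tsv", "barcodes.tsv.gz"))
    missing <- c(matrix = is.null(mtx), features = is.null(fts),
                 barcodes = is.null(bcs))
    if (any(missing))
      stop(sprintf("MTX directory %s is missing: %s", path,
                   paste(names(missing)[missing], collapse = ", ")))
    m <- Matrix::readMM(mtx)
    m <- methods::as(m, "CsparseMatrix")
    genes <- data.table::fread(fts, header = FALSE, data.table = FALSE)[[1]]
    barcodes <- data.table::fread(bcs, header = FALSE, data.table = FALSE)[[1]]
    if (length(genes) != nrow(m))
      stop("features file length does not match matrix rows")
    if (length(barcodes) != ncol(m))
      stop("barcodes file length does not match matrix columns")
  } else {
    m <- .read_table_file(path, sep = if (format == "csv") "," else "\t")
    genes <- rownames(m)
    barcodes <- colnames(m)
    rownames(m) <- colnames(m) <- NULL
  }
  if (spotsAsRows) {
    m <- Matrix::t(m)
    tmp <- genes; genes <- barcodes; barcodes <- tmp
  }
  if (is.matrix(m) && all(abs(m - round(m)) < 1e-12)) m <- round(m)
  ExpressionMatrix(m, geneIds = genes, spotIds = barcodes, state = "raw_counts")
}

#' Write an expression matrix
#'
#' Inverse of [readExpression()]; round-trips element-wise exactly for all
#' three dialects.
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output directory (`mtx_dir`) or file (`csv`/`tsv`).
#' @param format one of `"mtx_dir"`, `"csv"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path, format = c("mtx_dir", "csv", "tsv")) {
  format <- match.arg(format)
  v <- exprValues(x)
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(v, sparse = TRUE), "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(geneIds(x), file.path(path, "features.tsv"))
    writeLines(spotIds(x), file.path(path, "barcodes.tsv"))
  } else {
    df <- data.frame(gene_id = geneIds(x), as.matrix(v), check.names = FALSE)
    colnames(df) <- c("gene_id", spotIds(x))
    data.table::fwrite(df, path, sep = if (format == "csv") "," else "\t")
  }
  invisible(path)
}

#' Read / write spot coordinates
#'
#' Coordinate tables have columns `spot_id`, `x`, `y`; the separator follows
#' the file extension (`.csv` comma, otherwise tab).
#'
#' @param path file path.
#' @return A [SpatialCoords-class].
#' @export
readCoords <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("spot_id", "x", "y")
  if (!all(need %in% colnames(df)))
    stop("coordinate file must have columns spot_id, x, y")
  SpatialCoords(df$spot_id, cbind(x = as.numeric(df$x), y = as.numeric(df$y)))
}

#' @rdname readCoords
#' @param coords a [SpatialCoords-class].
#' @export
writeCoords <- function(coords, path) {
  df <- data.frame(spot_id = spotIds(coords), x = coords@xy[, 1],
                   y = coords@xy[, 2])
  data.table::fwrite(df, path, sep = if (grepl("\\.csv$", path)) "," else "\t")
  invisible(path)
}

.set_state <- function(x, state) {
  x@state <- state
  methods::validObject(x)
  x
}

#' Quality-control filtering of a raw count matrix
#'
#' Removes genes detected (value strictly positive) in fewer than
#' `minCellsPerGene` spots, then spots expressing fewer than
#' `minGenesPerCell` of the remaining genes. The gene filter runs first;
#' the order matters and is fixed. The removal counts are attached as the
#' `"qc_report"` attribute (a data.frame of step / removed / remaining).
#'
#' @param x raw-count [ExpressionMatrix-class].
#' @param minCellsPerGene detection threshold per gene (default 3 cells).
#' @param minGenesPerCell expressed-gene threshold per spot (default 100).
#' @return Filtered [ExpressionMatrix-class], state `"raw_counts"`.
#' @export
qcFilter <- function(x, minCellsPerGene = 3, minGenesPerCell = 100) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (exprState(x) != "raw_counts")
    stop("qcFilter requires state 'raw_counts'")
  v <- exprValues(x)
  detectedIn <- Matrix::rowSums(v > 0)
  keepGenes <- detectedIn >= minCellsPerGene
  if (!any(keepGenes)) stop("empty matrix after QC (all genes removed)")
  v2 <- v[keepGenes, , drop = FALSE]
  genesPerSpot <- Matrix::colSums(v2 > 0)
  keepSpots <- genesPerSpot >= minGenesPerCell
  if (!any(keepSpots)) stop("empty matrix after QC (all spots removed)")
  out <- ExpressionMatrix(v2[, keepSpots, drop = FALSE],
                          geneIds = geneIds(x)[keepGenes],
                          spotIds = spotIds(x)[keepSpots],
                          state = "raw_counts")
  attr(out, "qc_report") <- data.frame(
    step = c("gene_filter", "cell_filter"),
    items_removed = c(sum(!keepGenes), sum(!keepSpots)),
    items_remaining = c(sum(keepGenes), sum(keepSpots)))
  out
}

#' Write the QC report attached by qcFilter
#'
#' @param x an [ExpressionMatrix-class] returned by [qcFilter()].
#' @param path output TSV path.
#' @export
writeQcReport <- function(x, path) {
  rep <- attr(x, "qc_report")
  if (is.null(rep)) stop("no qc_report attribute; run qcFilter first")
  data.table::fwrite(rep, path, sep = "\t")
  invisible(path)
}

#' Total-count normalization and log transform
#'
#' Each spot column is divided by its total, multiplied by `scale`
#' (default 1e4) and transformed by `log(1 + v)`, so every spot carries the
#' same pre-log total.
#'
#' @param x post-QC raw-count [ExpressionMatrix-class].
#' @param scale target per-spot total before the log (default `1e4`).
#' @return An [ExpressionMatrix-class] with state `"log_transformed"`.
#' @export
normalizeLog <- function(x, scale = 1e4) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (exprState(x) != "raw_counts")
    stop("normalizeLog requires state 'raw_counts'")
  if (scale <= 0) stop("scale must be positive")
  v <- exprValues(x)
  totals <- Matrix::colSums(v)
  if (any(totals == 0))
    stop(sprintf("zero-total spot column(s): %s",
                 paste(spotIds(x)[totals == 0], collapse = ", ")))
  if (is(v, "sparseMatrix")) {
    v <- methods::as(v, "CsparseMatrix")
    v@x <- log1p(v@x / rep.int(totals, diff(v@p)) * scale)
  } else {
    v <- log1p(sweep(v, 2, totals, "/") * scale)
  }
  out <- ExpressionMatrix(v, geneIds = geneIds(x), spotIds = spotIds(x),
                          state = "log_transformed")
  out@state <- "log_transformed"
  out
}

.dispersion_scores <- function(v, nBins = 20L) {
  # Seurat-flavour normalized dispersion on the de-logged values:
  # dispersion = var/mean per gene, z-scored within mean-quantile bins.
  e <- if (is(v, "sparseMatrix")) expm1(as.matrix(v)) else expm1(v)
  mu <- rowMeans(e)
  vr <- apply(e, 1, var)
  disp <- ifelse(mu > 0, vr / mu, 0)
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = nBins + 1L)))
  bins <- if (length(br) > 2) cut(mu, breaks = br, include.lowest = TRUE)
          else factor(rep(1, length(mu)))
  z <- disp
  for (b in levels(bins)) {
    idx <- which(bins == b)
    mb <- mean(disp[idx]); sb <- stats::sd(disp[idx])
    z[idx] <- if (is.na(sb) || sb == 0) 0 else (disp[idx] - mb) / sb
  }
  list(z = z, mu = mu)
}

#' Select highly variable genes
#'
#' Keeps the `nTop` genes with highest normalized dispersion: per-gene
#' variance/mean of the de-logged (`expm1`) expression, z-scored within 20
#' mean-quantile bins. Ties break toward higher mean, then input order.
#' Gene order is preserved; when M <= `nTop` the input is returned with
#' only the state advanced.
#'
#' @param x log-transformed [ExpressionMatrix-class].
#' @param nTop number of genes to keep (default 3000).
#' @return An [ExpressionMatrix-class] with state `"hvg_subset"`.
#' @export
selectHvg <- function(x, nTop = 3000) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (exprState(x) != "log_transformed")
    stop("selectHvg requires state 'log_transformed'")
  if (nTop < 1) stop("nTop must be >= 1")
  v <- exprValues(x)
  if (nrow(v) <= nTop) return(.set_state(x, "hvg_subset"))
  sc <- .dispersion_scores(v)
  ord <- order(-sc$z, -sc$mu, seq_along(sc$z))
  keep <- sort(ord[seq_len(nTop)])
  out <- ExpressionMatrix(v[keep, , drop = FALSE],
                          geneIds = geneIds(x)[keep],
                          spotIds = spotIds(x),
                          state = "log_transformed")
  out@state <- "hvg_subset"
  methods::validObject(out)
  out
}

#' Standard preprocessing chain
#'
#' Convenience wrapper running [qcFilter()], [normalizeLog()] and
#' [selectHvg()] with the standard defaults; the combined QC report is
#' attached as the `"qc_report"` attribute.
#'
#' @param x raw-count [ExpressionMatrix-class].
#' @param minCellsPerGene,minGenesPerCell QC thresholds.
#' @param scale normalization scale factor.
#' @param nTop number of highly variable genes.
#' @return An [ExpressionMatrix-class] with state `"hvg_subset"`.
#' @export
preprocessExpression <- function(x, minCellsPerGene = 3, minGenesPerCell = 100,
                                 scale = 1e4, nTop = 3000) {
  q <- qcFilter(x, minCellsPerGene, minGenesPerCell)
  rep <- attr(q, "qc_report")
  out <- selectHvg(normalizeLog(q, scale), nTop)
  attr(out, "qc_report") <- rbind(rep, data.frame(
    step = "hvg_select",
    items_removed = nrow(q) - nrow(out),
    items_remaining = nrow(out)))
  out
}
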