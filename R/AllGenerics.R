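#' @name accessors
#' @title Accessors for mcist classes
#' @description Slot accessors; user code should use these rather than `@`.
#' @param x an mcist object.
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) x@geneIds)

#' @rdname accessors
#' @export
setGeneric("spotIds", function(x) standardGeneric("spotIds"))
#' @rdname accessors
#' @export
setMethod("spotIds", "ExpressionMatrix", function(x) x@spotIds)
#' @rdname accessors
#' @export
setMethod("spotIds", "SpatialCoords", function(x) x@spotIds)
#' @rdname accessors
#' @export
setMethod("spotIds", "SpatialEmbedding", function(x) x@spotIds)
#' @rdname accessors
#' @export
setMethod("spotIds", "ClusterLabels", function(x) x@spotIds)

#' @rdname accessors
#' @export
setGeneric("exprState", function(x) standardGeneric("exprState"))
#' @rdname accessors
#' @export
setMethod("exprState", "ExpressionMatrix", function(x) x@state)

#' @rdname accessors
#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

#' @rdname accessors
#' @export
setGeneric("coordsXY", function(x) standardGeneric("coordsXY"))
#' @rdname accessors
#' @export
setMethod("coordsXY", "SpatialCoords", function(x) x@xy)

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setMethod("graphEdges", "KnnGraph", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setMethod("adjacency", "WeightedAdjacency", function(x) x@W)

#' @rdname accessors
#' @export
setGeneric("laplacianMatrix", function(x) standardGeneric("laplacianMatrix"))
#' @rdname accessors
#' @export
setMethod("laplacianMatrix", "GraphLaplacian", function(x) x@L)
#' @rdname accessors
#' @export
setMethod("laplacianMatrix", "AccumulatedLaplacian", function(x) x@LP)

#' @rdname accessors
#' @export
setGeneric("filtrationScales", function(x) standardGeneric("filtrationScales"))
#' @rdname accessors
#' @export
setMethod("filtrationScales", "LaplacianFiltration", function(x) x@ks)

#' @rdname accessors
#' @export
setGeneric("filtrationLaplacians", function(x) standardGeneric("filtrationLaplacians"))
#' @rdname accessors
#' @export
setMethod("filtrationLaplacians", "LaplacianFiltration", function(x) x@laplacians)

#' @rdname accessors
#' @export
setGeneric("loadings", function(x) standardGeneric("loadings"))
#' @rdname accessors
#' @export
setMethod("loadings", "TpcaResult", function(x) x@U)

#' @rdname accessors
#' @export
setGeneric("embedding", function(x) standardGeneric("embedding"))
#' @rdname accessors
#' @export
setMethod("embedding", "TpcaResult", function(x) x@Q)
#' @rdname accessors
#' @export
setMethod("embedding", "SpatialEmbedding", function(x) x@Z)

#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
#' @rdname accessors
#' @export
setMethod("objectiveTrace", "TpcaResult", function(x) x@objectiveTrace)

#' @rdname accessors
#' @export
setGeneric("alignedFeatures", function(x) standardGeneric("alignedFeatures"))
#' @rdname accessors
#' @export
setMethod("alignedFeatures", "AlignedEmbedding", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("canonicalValues", function(x) standardGeneric("canonicalValues"))
#' @rdname accessors
#' @export
setMethod("canonicalValues", "AlignedEmbedding", function(x) x@lambdas)

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterLabels", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ConsensusResult", function(x) x@domains@labels)

#' @rdname accessors
#' @export
setGeneric("coAssociationMatrix", function(x) standardGeneric("coAssociationMatrix"))
#' @rdname accessors
#' @export
setMethod("coAssociationMatrix", "CoAssociation", function(x) x@Cmat)

#' @rdname accessors
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))
#' @rdname accessors
#' @export
setMethod("domains", "ConsensusResult", function(x) x@domains)

#' @rdname accessors
#' @export
setGeneric("rsiValue", function(x) standardGeneric("rsiValue"))
#' @rdname accessors
#' @export
setMethod("rsiValue", "RsiReport", function(x) x@rsi)

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d spots [%s]\n",
              nrow(object@values), ncol(object@values), object@state))
})
setMethod("show", "KnnGraph", function(object) {
  cat(sprintf("KnnGraph: n=%d, k=%d, %d edges (%s)\n",
              object@n, object@k, nrow(object@edges), object@metric))
})
setMethod("show", "LaplacianFiltration", function(object) {
  cat(sprintf("LaplacianFiltration: n=%d, scales k = %s\n",
              object@n, paste(object@ks, collapse = ", ")))
})
setMethod("show", "TpcaResult", function(object) {
  cat(sprintf("TpcaResult: Q %d x %d, %d iterations, %sconverged, objective %.6g\n",
              nrow(object@Q), ncol(object@Q), object@nIter,
              if (object@converged) "" else "NOT ",
              utils::tail(object@objectiveTrace, 1)))
})
setMethod("show", "AlignedEmbedding", function(object) {
  cat(sprintf("AlignedEmbedding: %d x %d features, c=%d, top lambda %.4f\n",
              nrow(object@features), ncol(object@features),
              length(object@lambdas),
              if (length(object@lambdas)) object@lambdas[1] else NA_real_))
})
setMethod("show", "ClusterLabels", function(object) {
  cat(sprintf("ClusterLabels: %d spots, %d classes\n",
              length(object@labels), length(unique(object@labels))))
})
setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: %d spots, %d domains, %d ensemble members%s\n",
              length(object@domains@labels),
              length(unique(object@domains@labels)),
              length(object@memberLabelsets),
              if (!is.na(object@selectedEmbedding))
                sprintf(", RSI-selected member %d", object@selectedEmbedding)
              else ""))
})
setMethod("show", "SynthDataset", function(object) {
  cat(sprintf("SynthDataset: %d genes x %d spots, %d domains\n",
              nrow(object@expression@values), ncol(object@expression@values),
              length(unique(object@truth@labels))))
})
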