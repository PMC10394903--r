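#' Accessors for package classes
#'
#' \code{exprValues}, \code{geneIds}, \code{columnIds} and \code{unitTag}
#' access \linkS4class{ExpressionMatrix} content; \code{compValues},
#' \code{sampleIds} and \code{celltypeIds} access
#' \linkS4class{CompositionMatrix} content; \code{profiles},
#' \code{cellCounts} and \code{markers} access
#' \linkS4class{ClusterReference} content.
#'
#' @param x the object.
#' @return the requested component.
#' @name accessors
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
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("geneIds", "ClusterReference", function(x) rownames(x@profiles@values))

#' @rdname accessors
#' @export
setGeneric("columnIds", function(x) standardGeneric("columnIds"))
#' @rdname accessors
#' @export
setMethod("columnIds", "ExpressionMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setGeneric("unitTag", function(x) standardGeneric("unitTag"))
#' @rdname accessors
#' @export
setMethod("unitTag", "ExpressionMatrix", function(x) x@unitTag)

#' @rdname accessors
#' @export
setGeneric("compValues", function(x) standardGeneric("compValues"))
#' @rdname accessors
#' @export
setMethod("compValues", "CompositionMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setMethod("sampleIds", "CompositionMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("sampleIds", "CellLabelTable", function(x) x@sampleId)

#' @rdname accessors
#' @export
setGeneric("celltypeIds", function(x) standardGeneric("celltypeIds"))
#' @rdname accessors
#' @export
setMethod("celltypeIds", "CompositionMatrix", function(x) colnames(x@values))

#' @rdname accessors
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))
#' @rdname accessors
#' @export
setMethod("profiles", "ClusterReference", function(x) x@profiles)

#' @rdname accessors
#' @export
setGeneric("cellCounts", function(x) standardGeneric("cellCounts"))
#' @rdname accessors
#' @export
setMethod("cellCounts", "ClusterReference", function(x) x@cellCounts)

#' @rdname accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))
#' @rdname accessors
#' @export
setMethod("markers", "ClusterReference", function(x) x@markers)

#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setMethod("cellIds", "CellLabelTable", function(x) x@cellId)

#' @rdname accessors
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))
#' @rdname accessors
#' @export
setMethod("clusterIds", "CellLabelTable", function(x) x@clusterId)

#' @rdname accessors
#' @export
setGeneric("solverMetadata", function(x) standardGeneric("solverMetadata"))
#' @rdname accessors
#' @export
setMethod("solverMetadata", "CompositionMatrix", function(x) x@metadata)

#' Coerce a CellLabelTable to data.frame
#'
#' @param x a \linkS4class{CellLabelTable}.
#' @param row.names,optional,... ignored (base signature).
#' @return data.frame with columns cell_id, sample_id, cluster_id,
#'   mito_fraction, ribo_fraction.
#' @export
as.data.frame.CellLabelTable <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(cell_id = x@cellId, sample_id = x@sampleId,
             cluster_id = x@clusterId, mito_fraction = x@mitoFraction,
             ribo_fraction = x@riboFraction, stringsAsFactors = FALSE)
}

#' @export
setMethod("length", "CellLabelTable", function(x) length(x@cellId))

#' Subset a CellLabelTable by cell
#'
#' @param x a \linkS4class{CellLabelTable}.
#' @param i logical, integer or character (cell id) index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "CellLabelTable", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@cellId)
  new("CellLabelTable", cellId = x@cellId[i], sampleId = x@sampleId[i],
      clusterId = x@clusterId[i], mitoFraction = x@mitoFraction[i],
      riboFraction = x@riboFraction[i])
})

setMethod("show", "ExpressionMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("ExpressionMatrix: %d genes x %d columns [%s]\n",
              d[1], d[2], object@unitTag))
})

setMethod("show", "CellLabelTable", function(object) {
  cat(sprintf("CellLabelTable: %d cells, %d samples, %d clusters\n",
              length(object@cellId), length(unique(object@sampleId)),
              length(unique(object@clusterId))))
})

setMethod("show", "CompositionMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("CompositionMatrix (%s): %d samples x %d cell types\n",
              object@kind, d[1], d[2]))
  if (d[1] > 0) print(round(head(object@values, 6), 4))
})

setMethod("show", "ClusterReference", function(object) {
  cat(sprintf("ClusterReference: %d genes x %d clusters (%s cells)\n",
              nrow(object@profiles@values), ncol(object@profiles@values),
              format(sum(object@cellCounts))))
})

setMethod("show", "TransformModel", function(object) {
  cat(sprintf("TransformModel [%s]: %d modeled genes\n", object@mode,
              nrow(object@coefficients)))
})

setMethod("show", "ConcurrentDataset", function(object) {
  cat(sprintf("ConcurrentDataset: %d samples; bulk %d genes, single-cell %d genes x %d cells\n",
              ncol(object@bulk@values), nrow(object@bulk@values),
              nrow(object@scCounts@values), ncol(object@scCounts@values)))
})

setMethod("show", "BenchmarkResult", function(object) {
  cat(sprintf("BenchmarkResult: %s (bulk: %s, ref: %s) r = %s, RMSE = %.4g, n = %d\n",
              object@method, object@bulkNormalization,
              object@referenceNormalization,
              ifelse(is.na(object@pearsonR), paste0("NA (", object@reason, ")"),
                     sprintf("%.4f", object@pearsonR)),
              object@rmse, as.integer(object@nPoints)))
})

setMethod("show", "MixtureDesign", function(object) {
  cat(sprintf("MixtureDesign: %d mixtures x %d cell types, %d genes (seed %d)\n",
              nrow(object@proportions), ncol(object@proportions),
              as.integer(object@nGenes), as.integer(object@seed)))
  print(round(object@proportions, 4))
})
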