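#' Accessors for package classes
#'
#' @param x an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("diseaseNames", function(x) standardGeneric("diseaseNames"))

#' @rdname accessors
#' @export
setGeneric("lncRNANames", function(x) standardGeneric("lncRNANames"))

#' @rdname accessors
#' @export
setGeneric("dagNodes", function(x) standardGeneric("dagNodes"))

#' @rdname accessors
#' @export
setGeneric("hierarchyRecords", function(x) standardGeneric("hierarchyRecords"))

#' @rdname accessors
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))

#' @rdname accessors
#' @export
setGeneric("pairFeatures", function(x) standardGeneric("pairFeatures"))

#' @rdname accessors
#' @export
setGeneric("lossTrace", function(x) standardGeneric("lossTrace"))

#' @rdname accessors
setMethod("diseaseNames", "InteractionMatrix", function(x) rownames(x@assoc))

#' @rdname accessors
setMethod("lncRNANames", "InteractionMatrix", function(x) colnames(x@assoc))

#' @rdname accessors
setMethod("diseaseNames", "SyntheticBundle", function(x) diseaseNames(x@interaction))

#' @rdname accessors
setMethod("lncRNANames", "SyntheticBundle", function(x) lncRNANames(x@interaction))

#' @rdname accessors
setMethod("dagNodes", "DiseaseDAG", function(x) x@nodes)

#' @rdname accessors
setMethod("hierarchyRecords", "DiseaseHierarchy", function(x) x@records)

#' @rdname accessors
setMethod("pairLabels", "PairFeatureSet", function(x) x@labels)

#' @rdname accessors
setMethod("pairFeatures", "PairFeatureSet", function(x) x@features)

#' @rdname accessors
setMethod("lossTrace", "EncoderModel", function(x) x@lossTrace)

#' @rdname accessors
setMethod("lossTrace", "BoostedModel", function(x) x@lossTrace)

#' @describeIn accessors the binary association matrix itself.
#' @export
setMethod("as.matrix", "InteractionMatrix", function(x, ...) x@assoc)

setMethod("show", "InteractionMatrix", function(object) {
  m <- object@assoc
  cat(sprintf("InteractionMatrix: %d diseases x %d lncRNAs, %d known associations (density %.3g)\n",
              nrow(m), ncol(m), sum(m), mean(m)))
})

setMethod("show", "DiseaseHierarchy", function(object) {
  n <- length(object@records)
  cat(sprintf("DiseaseHierarchy: %d diseases, %d tree codes\n",
              n, sum(lengths(object@records))))
})

setMethod("show", "DiseaseDAG", function(object) {
  if (length(object@nodes) == 0) {
    cat(sprintf("DiseaseDAG '%s': empty (no hierarchy record)\n", object@disease))
  } else {
    cat(sprintf("DiseaseDAG '%s': %d nodes, %d target code(s)\n",
                object@disease, length(object@nodes), length(object@targets)))
  }
})

setMethod("show", "PairFeatureSet", function(object) {
  cat(sprintf("PairFeatureSet: %d pairs x %d features, layout %s [%s], %d positives\n",
              nrow(object@features), ncol(object@features), object@layout,
              paste(object@blocks, collapse = "+"), sum(object@labels)))
})

setMethod("show", "EncoderModel", function(object) {
  cat(sprintf("EncoderModel: %d -> %d, %d epochs, final loss %.4g\n",
              nrow(object@W1), object@latentDim, length(object@lossTrace),
              utils::tail(object@lossTrace, 1)))
})

setMethod("show", "BoostedModel", function(object) {
  cat(sprintf("BoostedModel: %d trees, eta %.3g, F0 %.4g, final deviance %.4g\n",
              length(object@trees), object@learningRate, object@f0,
              if (length(object@lossTrace)) utils::tail(object@lossTrace, 1) else NA_real_))
})

setMethod("show", "SyntheticBundle", function(object) {
  cat(sprintf("SyntheticBundle: %d diseases x %d lncRNAs, %d clusters, %d associations\n",
              nrow(object@interaction@assoc), ncol(object@interaction@assoc),
              max(object@diseaseCluster), sum(object@interaction@assoc)))
})
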