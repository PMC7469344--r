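#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib lncDiseaseBoost, .registration = TRUE
NULL

#' InteractionMatrix: known lncRNA-disease associations
#'
#' Binary adjacency matrix with diseases on the rows and lncRNAs on the
#' columns; entry (i, j) is 1 when disease i is known to be associated with
#' lncRNA j. The matrix is the basis of every interaction-profile kernel and
#' supplies the labels of the classifier.
#'
#' @slot assoc binary numeric matrix (diseases x lncRNAs) with complete
#'   dimnames.
#' @export
setClass("InteractionMatrix", representation(assoc = "matrix"))

setValidity("InteractionMatrix", function(object) {
  m <- object@assoc
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("assoc must carry disease rownames and lncRNA colnames")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    return("duplicate disease or lncRNA identifiers")
  if (!all(m %in% c(0, 1)))
    return("all entries must be 0 or 1")
  TRUE
})

#' DiseaseHierarchy: MeSH-style tree-code records
#'
#' Maps each disease (whitespace-normalised, lower-cased key) to its set of
#' dot-delimited tree codes, e.g. \code{"C04.557.465"}. A disease may carry
#' several codes; diseases absent from the hierarchy simply have no record
#' and yield empty DAGs downstream.
#'
#' @slot records named list; each element a character vector of tree codes.
#' @export
setClass("DiseaseHierarchy", representation(records = "list"))

setValidity("DiseaseHierarchy", function(object) {
  r <- object@records
  if (length(r) && is.null(names(r))) return("records must be named by disease")
  ok <- vapply(r, function(x) is.character(x) && length(x) >= 1 &&
                 all(grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", x)), logical(1))
  if (!all(ok)) return("every record needs >= 1 well-formed dot-delimited code")
  TRUE
})

#' DiseaseDAG: a disease and all its hierarchy ancestors
#'
#' Nodes are tree-code prefixes; the target nodes are the disease's own full
#' codes. Every non-target node lies on a directed path (one-segment code
#' extensions) towards a target, so the graph is acyclic by construction.
#'
#' @slot disease the disease identifier the DAG describes.
#' @slot nodes character vector of code prefixes (the node set D(d)).
#' @slot targets the disease's own full codes (contribution 1 nodes).
#' @slot children named list mapping each node to its child nodes in the DAG.
#' @export
setClass("DiseaseDAG", representation(disease = "character", nodes = "character",
                                      targets = "character", children = "list"))

setValidity("DiseaseDAG", function(object) {
  if (length(object@nodes) == 0) return(TRUE) # empty DAG is legal (flagged upstream)
  if (!all(object@targets %in% object@nodes)) return("targets must be nodes")
  TRUE
})

#' PairFeatureSet: labelled per-pair feature vectors
#'
#' One row per (disease, lncRNA) pair, assembled from the similarity and
#' interaction blocks of a named feature layout.
#'
#' @slot features numeric matrix, one row per pair.
#' @slot labels integer 0/1 vector, one per pair.
#' @slot pairs two-column integer matrix of (disease index, lncRNA index).
#' @slot layout layout name (e.g. "FHN").
#' @slot blocks character vector of block names in concatenation order.
#' @export
setClass("PairFeatureSet", representation(features = "matrix", labels = "integer",
                                          pairs = "matrix", layout = "character",
                                          blocks = "character"))

setValidity("PairFeatureSet", function(object) {
  if (nrow(object@features) != length(object@labels))
    return("labels length must match feature rows")
  if (nrow(object@pairs) != nrow(object@features))
    return("pairs must match feature rows")
  if (!all(object@labels %in% c(0L, 1L))) return("labels must be 0/1")
  if (any(!is.finite(object@features))) return("features must be finite")
  TRUE
})

#' EncoderModel: single hidden-layer sigmoid autoencoder
#'
#' Encoder h(x) = sigmoid(W1 x + b1), decoder g(k) = sigmoid(W2 k + b2),
#' trained by mini-batch gradient descent on the element-wise cross-entropy
#' between the (min-max scaled) input and its reconstruction. The min-max
#' scaler fitted on the training rows is stored with the model.
#'
#' @slot W1,b1 encoder weights (input x latent) and bias.
#' @slot W2,b2 decoder weights (latent x input) and bias.
#' @slot latentDim encoded dimensionality.
#' @slot lossTrace mean cross-entropy per epoch.
#' @slot scaleMin,scaleRange per-column min-max scaler parameters.
#' @export
setClass("EncoderModel", representation(W1 = "matrix", b1 = "numeric",
                                        W2 = "matrix", b2 = "numeric",
                                        latentDim = "integer", lossTrace = "numeric",
                                        scaleMin = "numeric", scaleRange = "numeric"))

setValidity("EncoderModel", function(object) {
  if (ncol(object@W1) != object@latentDim) return("W1 must map input -> latent")
  if (nrow(object@W2) != object@latentDim || ncol(object@W2) != nrow(object@W1))
    return("W2 must map latent -> input")
  TRUE
})

#' BoostedModel: gradient boosted regression trees
#'
#' Additive model F(x) = F0 + eta * sum_m gamma_m(x), where each gamma_m is a
#' depth-bounded least-squares regression tree fitted to the negative
#' gradient of the binomial deviance, with per-leaf Newton step values.
#' Probabilities are the logistic transform of F(x).
#'
#' @slot f0 initial score (log-odds of the positive rate).
#' @slot trees list of fitted trees (split records with leaf values).
#' @slot learningRate shrinkage eta.
#' @slot lossTrace training binomial deviance after each tree.
#' @slot nFeatures training feature dimension.
#' @slot seed seed recorded with the model (no subsampling is used, so it
#'   affects nothing beyond provenance).
#' @export
setClass("BoostedModel", representation(f0 = "numeric", trees = "list",
                                        learningRate = "numeric", lossTrace = "numeric",
                                        nFeatures = "integer", seed = "integer"))

#' SyntheticBundle: planted-cluster benchmark instance
#'
#' A generated disease hierarchy plus a binary association matrix in which
#' diseases and lncRNAs of the same planted cluster are preferentially
#' linked, together with the ground-truth cluster assignments.
#'
#' @slot hierarchy a \linkS4class{DiseaseHierarchy}.
#' @slot interaction an \linkS4class{InteractionMatrix}.
#' @slot diseaseCluster,lncCluster named integer cluster assignments.
#' @slot spec the generating specification (list, see [syntheticSpec()]).
#' @export
setClass("SyntheticBundle", representation(hierarchy = "DiseaseHierarchy",
                                           interaction = "InteractionMatrix",
                                           diseaseCluster = "integer",
                                           lncCluster = "integer",
                                           spec = "list"))
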