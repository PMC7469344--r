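#' Build the ancestor DAG of a disease
#'
#' Expands every tree code of the disease into its chain of dot-delimited
#' prefixes. Nodes are the prefix strings; edges connect each prefix to its
#' one-segment extension; the disease's own full codes are the target nodes.
#' A disease with several codes gets the union of all prefix chains, the
#' usual MeSH construction. Diseases without a hierarchy record yield an
#' empty DAG with a warning.
#'
#' @param disease disease identifier (matched to hierarchy records
#'   case-insensitively with whitespace collapsed).
#' @param hierarchy a \linkS4class{DiseaseHierarchy}.
#' @return a \linkS4class{DiseaseDAG}.
#' @examples
#' h <- new("DiseaseHierarchy", records = list(glioma = "C04.557.465"))
#' buildDiseaseDAG("glioma", h)
#' @export
buildDiseaseDAG <- function(disease, hierarchy) {
  codes <- hierarchy@records[[normalizeDiseaseKey(disease)]]
  if (is.null(codes)) {
    warning("disease '", disease, "' has no hierarchy record: empty DAG")
    return(new("DiseaseDAG", disease = disease, nodes = character(),
               targets = character(), children = list()))
  }
  nodes <- unique(unlist(lapply(codes, function(code) {
    seg <- strsplit(code, ".", fixed = TRUE)[[1]]
    vapply(seq_along(seg), function(k) paste(seg[1:k], collapse = "."), character(1))
  })))
  children <- lapply(nodes, function(p) {
    kids <- nodes[startsWith(nodes, paste0(p, ".")) &
                    !grepl("\\.", substring(nodes, nchar(p) + 2))]
    kids
  })
  names(children) <- nodes
  new("DiseaseDAG", disease = disease, nodes = nodes, targets = codes,
      children = children)
}

#' Decay-based semantic contributions within a DAG
#'
#' The target node(s) contribute 1; every ancestor k contributes
#' \code{max(delta * contribution(child))} over its children inside the DAG,
#' so a node's contribution is \code{delta ^ (shortest path to a target)}.
#' The total is the sum over all nodes.
#'
#' @param dag a non-empty \linkS4class{DiseaseDAG}.
#' @param delta semantic contribution decay factor in (0, 1); default 0.5.
#' @return a list with \code{values} (named numeric per node) and
#'   \code{total} (their sum).
#' @export
localContributions <- function(dag, delta = 0.5) {
  stopifnot2(delta > 0 && delta < 1, "delta must lie in (0,1)")
  if (length(dag@nodes) == 0) stop("no semantic record for '", dag@disease, "'")
  vals <- stats::setNames(rep(NA_real_, length(dag@nodes)), dag@nodes)
  ds <- function(node) {
    if (!is.na(vals[[node]])) return(vals[[node]])
    v <- if (node %in% dag@targets) 1 else {
      kids <- dag@children[[node]]
      max(vapply(kids, function(k) delta * ds(k), numeric(1)))
    }
    vals[[node]] <<- v
    v
  }
  for (n in dag@nodes) ds(n)
  list(values = vals, total = sum(vals))
}

#' Decay-based semantic similarity of two diseases
#'
#' Shared ancestors contribute the sum of their contributions in each DAG,
#' normalised by the two totals; identical DAGs score 1, disjoint ones 0.
#' Either DAG empty scores 0 (the Gaussian-kernel fallback applies at
#' fusion time).
#'
#' @param dagI,dagJ \linkS4class{DiseaseDAG}s.
#' @param delta decay factor, see [localContributions()].
#' @return similarity in [0, 1].
#' @export
disss1Pair <- function(dagI, dagJ, delta = 0.5) {
  if (length(dagI@nodes) == 0 || length(dagJ@nodes) == 0) return(0)
  ci <- localContributions(dagI, delta)
  cj <- localContributions(dagJ, delta)
  shared <- intersect(dagI@nodes, dagJ@nodes)
  if (length(shared) == 0) return(0)
  sum(ci$values[shared] + cj$values[shared]) / (ci$total + cj$total)
}

#' Frequency-based (information content) contribution of a hierarchy term
#'
#' With the default \code{sign = "negative_log"} the contribution of a term
#' is \code{-log(n / N)}, where n counts the disease DAGs containing the
#' term and N is the corpus size: a term shared by every disease carries no
#' information, a rare term carries much. \code{sign = "as_printed"} returns
#' \code{log(n / N)} for auditability.
#'
#' @param term a tree-code prefix.
#' @param dags list of \linkS4class{DiseaseDAG}s (the corpus; empty DAGs count
#'   towards N but contain no terms).
#' @param sign \code{"negative_log"} (default) or \code{"as_printed"}.
#' @return a real contribution value.
#' @export
globalContribution <- function(term, dags, sign = c("negative_log", "as_printed")) {
  sign <- match.arg(sign)
  n <- sum(vapply(dags, function(d) term %in% d@nodes, logical(1)))
  if (n == 0) stop("term '", term, "' occurs in no disease DAG")
  ic <- log(n / length(dags))
  if (sign == "negative_log") -ic else ic
}

#' Frequency-based semantic similarity of two diseases
#'
#' Same normalised shared-ancestor form as [disss1Pair()], but every term
#' carries its corpus-level contribution ([globalContribution()]) instead of
#' a decayed local one. When both totals are zero (a degenerate corpus where
#' all shared terms are universal), the score is 1 for i = j and 0 otherwise.
#'
#' @param dagI,dagJ \linkS4class{DiseaseDAG}s.
#' @param contributions named numeric of per-term contributions covering all
#'   terms of both DAGs.
#' @return similarity score (in [0, 1] under the negative-log convention).
#' @export
disss2Pair <- function(dagI, dagJ, contributions) {
  if (length(dagI@nodes) == 0 || length(dagJ@nodes) == 0) return(0)
  d2i <- sum(contributions[dagI@nodes])
  d2j <- sum(contributions[dagJ@nodes])
  if (d2i + d2j == 0) return(if (identical(dagI@disease, dagJ@disease)) 1 else 0)
  shared <- intersect(dagI@nodes, dagJ@nodes)
  if (length(shared) == 0) return(0)
  2 * sum(contributions[shared]) / (d2i + d2j)
}

#' Disease semantic similarity matrices
#'
#' Computes both semantic similarity matrices over a set of diseases: the
#' decay-based variant (local information; contributions fall off with DAG
#' distance) and the frequency-based variant (global information; term
#' contributions are corpus information content). Diseases without a
#' hierarchy record get zero off-diagonal similarity; diagonals are 1.
#'
#' @param diseases character vector of disease identifiers (row/col order).
#' @param hierarchy a \linkS4class{DiseaseHierarchy}.
#' @param delta decay factor for the local variant.
#' @param sign sign convention for the global variant, see
#'   [globalContribution()].
#' @return list with symmetric matrices \code{DISSS1} and \code{DISSS2}.
#' @export
semanticSimilarityMatrices <- function(diseases, hierarchy, delta = 0.5,
                                       sign = c("negative_log", "as_printed")) {
  sign <- match.arg(sign)
  nd <- length(diseases)
  dags <- lapply(diseases, function(d)
    suppressWarnings(buildDiseaseDAG(d, hierarchy)))
  empty <- vapply(dags, function(d) length(d@nodes) == 0, logical(1))
  if (all(empty)) warning("no disease has a hierarchy record: zero semantic similarity")
  terms <- unique(unlist(lapply(dags, dagNodes)))
  dn <- list(diseases, diseases)

  if (length(terms) == 0) {
    z <- matrix(0, nd, nd, dimnames = dn); diag(z) <- 1
    return(list(DISSS1 = z, DISSS2 = z))
  }

  memb <- matrix(0, nd, length(terms), dimnames = list(diseases, terms))
  contr <- memb
  for (i in seq_len(nd)) {
    if (empty[i]) next
    memb[i, dags[[i]]@nodes] <- 1
    lc <- localContributions(dags[[i]], delta)
    contr[i, names(lc$values)] <- lc$values
  }

  d1 <- rowSums(contr)
  num1 <- contr %*% t(memb) + memb %*% t(contr)
  den1 <- outer(d1, d1, "+")
  s1 <- ifelse(den1 > 0, num1 / den1, 0)
  s1[empty, ] <- 0; s1[, empty] <- 0
  diag(s1) <- 1

  ic <- log(colSums(memb) / nd)
  if (sign == "negative_log") ic <- -ic
  d2 <- as.vector(memb %*% ic)
  num2 <- 2 * (memb %*% (ic * t(memb)))
  den2 <- outer(d2, d2, "+")
  s2 <- ifelse(den2 != 0, num2 / den2, 0)
  s2[empty, ] <- 0; s2[, empty] <- 0
  diag(s2) <- 1
  dimnames(s1) <- dimnames(s2) <- dn
  list(DISSS1 = s1, DISSS2 = s2)
}
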