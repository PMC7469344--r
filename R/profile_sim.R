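#' Disease sets associated with each lncRNA
#'
#' @param interaction an \linkS4class{InteractionMatrix}. In strict
#'   evaluation this is the training-fold matrix only.
#' @return named list mapping each lncRNA to the integer indices of its
#'   associated diseases (possibly empty).
#' @export
diseaseSets <- function(interaction) {
  m <- as.matrix(interaction)
  sets <- lapply(seq_len(ncol(m)), function(j) which(m[, j] == 1))
  names(sets) <- colnames(m)
  sets
}

#' Best-match association of a disease to a disease set
#'
#' @param d disease index (row of the semantic matrix).
#' @param targetSet non-empty integer vector of disease indices.
#' @param semantic disease semantic similarity matrix.
#' @return the maximum semantic similarity between \code{d} and any member
#'   of \code{targetSet}.
#' @export
bestMatchScore <- function(d, targetSet, semantic) {
  stopifnot2(length(targetSet) > 0, "target disease set is empty")
  max(semantic[d, targetSet])
}

#' Best-match-average functional similarity of two lncRNAs
#'
#' Each disease of lncRNA p is best-matched into the disease set of lncRNA
#' q and vice versa; the matched similarities are summed and divided by the
#' total set size m + n. Either set empty gives 0 (flagged at the matrix
#' level).
#'
#' @param p,q lncRNA names or indices into \code{sets}.
#' @param sets disease sets as returned by [diseaseSets()].
#' @param semantic disease semantic similarity matrix.
#' @return similarity in [0, 1] when \code{semantic} is.
#' @export
functionalSimilarityPair <- function(p, q, sets, semantic) {
  dp <- sets[[p]]; dq <- sets[[q]]
  if (length(dp) == 0 || length(dq) == 0) return(0)
  s1 <- sum(vapply(dp, bestMatchScore, numeric(1), targetSet = dq, semantic = semantic))
  s2 <- sum(vapply(dq, bestMatchScore, numeric(1), targetSet = dp, semantic = semantic))
  (s1 + s2) / (length(dp) + length(dq))
}

#' lncRNA functional similarity matrix
#'
#' Best-match-average similarity over all lncRNA pairs, computed from a
#' disease semantic similarity matrix (use the decay-based matrix for the
#' local variant, the frequency-based one for the global variant). Rows and
#' columns of lncRNAs with no associated disease are zero off-diagonal.
#'
#' @param interaction an \linkS4class{InteractionMatrix} (training fold in
#'   strict mode).
#' @param semantic disease semantic similarity matrix aligned with the
#'   interaction rows.
#' @return symmetric N_l x N_l matrix.
#' @export
functionalSimilarity <- function(interaction, semantic) {
  m <- as.matrix(interaction)
  stopifnot2(nrow(semantic) == nrow(m), "semantic matrix must match diseases")
  nl <- ncol(m)
  sets <- diseaseSets(interaction)
  sizes <- lengths(sets)
  # B[l, d] = best match of disease d into the disease set of lncRNA l
  B <- matrix(0, nl, nrow(m))
  for (l in seq_len(nl)) {
    if (sizes[l] > 0)
      B[l, ] <- apply(semantic[, sets[[l]], drop = FALSE], 1, max)
  }
  # C[p, q] = sum over diseases of p of their best match into set of q
  M <- t(m)                       # lncRNA x disease indicator
  C <- M %*% t(B)
  out <- (C + t(C)) / outer(sizes, sizes, "+")
  out[!is.finite(out)] <- 0       # both sets empty
  out[sizes == 0, ] <- 0
  out[, sizes == 0] <- 0
  dimnames(out) <- list(colnames(m), colnames(m))
  out
}

#' Gaussian interaction-profile kernel similarity
#'
#' Kernel \code{exp(-mu * ||u - v||^2)} over binary interaction profiles:
#' rows of the interaction matrix for diseases, columns for lncRNAs. The
#' bandwidth is \code{mu = muPrime / mean(||profile||^2)} under the default
#' scale-free rule, or \code{mu = muPrime * mean(||profile||^2)} with
#' \code{rule = "multiply_as_printed"}.
#'
#' @param interaction an \linkS4class{InteractionMatrix}.
#' @param axis \code{"diseases"} (row profiles) or \code{"lncrnas"} (column
#'   profiles).
#' @param muPrime bandwidth scale, default 0.5.
#' @param rule bandwidth normalisation rule.
#' @return symmetric similarity matrix with unit diagonal, entries in (0, 1].
#' @examples
#' im <- new("InteractionMatrix",
#'           assoc = matrix(c(1, 0, 0, 1), 2, 2,
#'                          dimnames = list(c("d1", "d2"), c("l1", "l2"))))
#' gipSimilarity(im, "diseases")[1, 2]  # exp(-1)
#' @export
gipSimilarity <- function(interaction, axis = c("diseases", "lncrnas"),
                          muPrime = 0.5, rule = c("divide", "multiply_as_printed")) {
  axis <- match.arg(axis)
  rule <- match.arg(rule)
  stopifnot2(muPrime > 0, "muPrime must be positive")
  p <- as.matrix(interaction)
  if (axis == "lncrnas") p <- t(p)
  norms <- rowSums(p^2)
  meanNorm <- mean(norms)
  if (rule == "divide") {
    if (meanNorm == 0) stop("bandwidth undefined: all interaction profiles are zero")
    mu <- muPrime / meanNorm
  } else {
    if (meanNorm == 0) message("zero mean profile norm: kernel degenerates to all-ones")
    mu <- muPrime * meanNorm
  }
  d2 <- outer(norms, norms, "+") - 2 * tcrossprod(p)
  d2[d2 < 0] <- 0
  k <- exp(-mu * d2)
  dimnames(k) <- list(rownames(p), rownames(p))
  k
}
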