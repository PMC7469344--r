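#' Fuse semantic/functional and Gaussian-kernel similarities
#'
#' Entry (i, j) is the average of the two semantic (or functional) matrices
#' whenever either carries information for the pair (\code{max(s1, s2) > 0}),
#' and falls back to the Gaussian interaction-profile kernel entry
#' otherwise. This fills the rows of entities missing from the hierarchy (or
#' with no associations) with kernel similarity.
#'
#' @param s1,s2 the two semantic (disease) or functional (lncRNA) matrices.
#' @param gip the matching Gaussian kernel matrix.
#' @return fused symmetric matrix.
#' @export
fuseSimilarity <- function(s1, s2, gip) {
  stopifnot2(all(dim(s1) == dim(s2)) && all(dim(s1) == dim(gip)),
             "similarity matrices must share a shape")
  out <- ifelse(pmax(s1, s2) > 0, (s1 + s2) / 2, gip)
  dimnames(out) <- dimnames(s1)
  out
}

#' Named feature-block layouts
#'
#' The fifteen block combinations used for the feature ablation: the full
#' heterogeneous network FHN (all five blocks), four tetramerous networks
#' THN1-4, six tripartite networks TriHN1-6 and four duplex networks
#' DHN1-4. Blocks are \code{DISSS} (disease semantic), \code{LNCFS} (lncRNA
#' functional), \code{LNCGS}/\code{DISGS} (Gaussian kernels) and
#' \code{LNCDIS} (raw interaction profiles). The mapping used here: THN1-4
#' drop one of LNCDIS, DISGS, LNCGS, LNCFS in turn; TriHN1-6 pair LNCDIS
#' with each two-subset of the four similarity blocks; DHN1-4 combine one
#' disease-side with one lncRNA-side similarity block.
#'
#' @return named list of character block vectors (15 presets).
#' @export
layoutPresets <- function() {
  sim <- c("DISSS", "LNCFS", "LNCGS", "DISGS")
  tri <- utils::combn(sim, 2, simplify = FALSE)
  presets <- c(
    list(FHN  = c(sim, "LNCDIS"),
         THN1 = sim,
         THN2 = c("DISSS", "LNCFS", "LNCGS", "LNCDIS"),
         THN3 = c("DISSS", "LNCFS", "DISGS", "LNCDIS"),
         THN4 = c("DISSS", "LNCGS", "DISGS", "LNCDIS")),
    stats::setNames(lapply(tri, function(b) c(b, "LNCDIS")), paste0("TriHN", 1:6)),
    list(DHN1 = c("DISSS", "LNCFS"),
         DHN2 = c("DISSS", "LNCGS"),
         DHN3 = c("DISGS", "LNCFS"),
         DHN4 = c("DISGS", "LNCGS"))
  )
  presets
}

#' Resolve a layout name or custom block set
#'
#' @param layout a preset name from [layoutPresets()] or a character vector
#'   of blocks (treated as a custom layout).
#' @return list with \code{name} and \code{blocks}.
#' @export
featureLayout <- function(layout) {
  presets <- layoutPresets()
  if (length(layout) == 1 && layout %in% names(presets))
    return(list(name = layout, blocks = presets[[layout]]))
  valid <- c("DISSS", "LNCFS", "LNCGS", "DISGS", "LNCDIS")
  stopifnot2(length(layout) > 0 && all(layout %in% valid),
             paste("custom layout blocks must be drawn from:",
                   paste(valid, collapse = ", ")))
  list(name = "custom", blocks = unique(layout))
}

#' Sample negative (unassociated) pairs
#'
#' Uniform draw without replacement over the zero entries of the interaction
#' matrix; reproducible for a fixed seed and independent of the caller's RNG
#' state.
#'
#' @param interaction an \linkS4class{InteractionMatrix}.
#' @param n number of negatives (must not exceed the zero-entry count).
#' @param seed RNG seed.
#' @return data.frame with integer columns \code{disease}, \code{lncRNA} and
#'   \code{label} (all 0).
#' @export
sampleNegativePairs <- function(interaction, n, seed = 0) {
  m <- as.matrix(interaction)
  zeros <- which(m == 0, arr.ind = TRUE)
  stopifnot2(n <= nrow(zeros),
             sprintf("requested %d negatives but only %d zero entries", n, nrow(zeros)))
  take <- withSeed(seed, sample.int(nrow(zeros), n))
  data.frame(disease = zeros[take, 1], lncRNA = zeros[take, 2], label = 0L)
}

#' Balanced labelled pair set
#'
#' All known associations as positives plus an equal number (by default) of
#' sampled negatives.
#'
#' @param interaction an \linkS4class{InteractionMatrix}.
#' @param nNegatives negatives to draw; defaults to the positive count
#'   (balanced 1:1 design).
#' @param seed RNG seed for the negative draw.
#' @return data.frame with columns \code{disease}, \code{lncRNA},
#'   \code{label}.
#' @export
labeledPairSet <- function(interaction, nNegatives = NULL, seed = 0) {
  m <- as.matrix(interaction)
  ones <- which(m == 1, arr.ind = TRUE)
  stopifnot2(nrow(ones) > 0, "interaction matrix has no positive pairs")
  if (is.null(nNegatives)) nNegatives <- nrow(ones)
  pos <- data.frame(disease = ones[, 1], lncRNA = ones[, 2], label = 1L)
  rbind(pos, sampleNegativePairs(interaction, nNegatives, seed))
}

#' Assemble per-pair feature vectors
#'
#' For pair (d, l) the feature row concatenates, in fixed order: the
#' disease-side similarity row of d (fused when both DISSS and DISGS are in
#' the layout, else the single selected matrix), the lncRNA-side similarity
#' row of l (analogous for LNCFS/LNCGS), and - when LNCDIS is in the layout -
#' the interaction profile of d over lncRNAs and/or of l over diseases.
#' With \code{maskTarget} the pair's own cell inside the interaction blocks
#' is zeroed so no row encodes its own label.
#'
#' @param pairs data.frame with integer columns \code{disease},
#'   \code{lncRNA}, \code{label}.
#' @param layout a preset name or block vector, see [featureLayout()].
#' @param similarities named list with the matrices the layout needs among
#'   \code{DISSS1}, \code{DISSS2}, \code{DISGS}, \code{LNCFS1},
#'   \code{LNCFS2}, \code{LNCGS}.
#' @param interaction the \linkS4class{InteractionMatrix} supplying
#'   interaction-profile blocks (training fold in strict mode).
#' @param maskTarget zero the pair's own position in interaction blocks.
#' @param interactionBlocks which interaction profiles to include:
#'   \code{"both"} (default), \code{"disease_row"} or \code{"lncrna_col"}.
#' @return a \linkS4class{PairFeatureSet}.
#' @export
assemblePairFeatures <- function(pairs, layout, similarities, interaction,
                                 maskTarget = TRUE,
                                 interactionBlocks = c("both", "disease_row", "lncrna_col")) {
  interactionBlocks <- match.arg(interactionBlocks)
  lay <- featureLayout(layout)
  blocks <- lay$blocks
  m <- as.matrix(interaction)
  di <- pairs$disease; lj <- pairs$lncRNA

  need <- function(nm) {
    stopifnot2(!is.null(similarities[[nm]]), paste("layout needs matrix", nm))
    similarities[[nm]]
  }
  parts <- list()

  hasDS <- "DISSS" %in% blocks; hasDG <- "DISGS" %in% blocks
  if (hasDS || hasDG) {
    dmat <- if (hasDS && hasDG) {
      fuseSimilarity(need("DISSS1"), need("DISSS2"), need("DISGS"))
    } else if (hasDS) (need("DISSS1") + need("DISSS2")) / 2 else need("DISGS")
    parts$disease <- dmat[di, , drop = FALSE]
  }
  hasLF <- "LNCFS" %in% blocks; hasLG <- "LNCGS" %in% blocks
  if (hasLF || hasLG) {
    lmat <- if (hasLF && hasLG) {
      fuseSimilarity(need("LNCFS1"), need("LNCFS2"), need("LNCGS"))
    } else if (hasLF) (need("LNCFS1") + need("LNCFS2")) / 2 else need("LNCGS")
    parts$lncrna <- lmat[lj, , drop = FALSE]
  }
  if ("LNCDIS" %in% blocks) {
    if (interactionBlocks %in% c("both", "disease_row")) {
      dr <- m[di, , drop = FALSE]
      if (maskTarget) dr[cbind(seq_along(lj), lj)] <- 0
      parts$interactionDisease <- dr
    }
    if (interactionBlocks %in% c("both", "lncrna_col")) {
      lc <- t(m)[lj, , drop = FALSE]
      if (maskTarget) lc[cbind(seq_along(di), di)] <- 0
      parts$interactionLnc <- lc
    }
  }
  feats <- do.call(cbind, unname(parts))
  rownames(feats) <- NULL
  new("PairFeatureSet", features = feats, labels = as.integer(pairs$label),
      pairs = cbind(disease = di, lncRNA = lj), layout = lay$name,
      blocks = blocks)
}
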