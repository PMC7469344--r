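#' Pipeline configuration
#'
#' Collects every tunable of the prediction pipeline with defaults matching
#' the published protocol: decay factor 0.5, kernel bandwidth scale 0.5,
#' autoencoder batch 128 / 100 epochs, tree depth 3, 1200 trees, learning
#' rate 0.1, seed 0, 8:2 hold-out split, full FHN feature layout.
#'
#' \code{mode} controls information leakage: \code{"strict"} rebuilds the
#' functional/kernel similarities and the autoencoder from the training fold
#' inside every split and masks each pair's own interaction cell;
#' \code{"paper_faithful"} precomputes them once from all known associations
#' (no masking), as a single up-front feature construction implies.
#'
#' @param delta semantic decay factor in (0, 1).
#' @param semSign sign convention of the frequency-based semantic variant.
#' @param muPrime Gaussian kernel bandwidth scale.
#' @param bandwidthRule kernel bandwidth normalisation rule.
#' @param layout feature layout name or block vector.
#' @param interactionBlocks which interaction-profile blocks to include.
#' @param maskTarget override target masking (default: ON in strict mode,
#'   OFF in paper-faithful mode).
#' @param latentDim,epochs,batchSize,aeLearningRate autoencoder settings.
#' @param depth,nTrees,learningRate booster settings.
#' @param threshold score threshold for confusion counts.
#' @param ratio training fraction of the hold-out split.
#' @param mode \code{"strict"} or \code{"paper_faithful"}.
#' @param seed run seed.
#' @return a list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(delta = 0.5, semSign = "negative_log",
                           muPrime = 0.5, bandwidthRule = "divide",
                           layout = "FHN", interactionBlocks = "both",
                           maskTarget = NULL,
                           latentDim = 128L, epochs = 100L, batchSize = 128L,
                           aeLearningRate = 0.5,
                           depth = 3L, nTrees = 1200L, learningRate = 0.1,
                           threshold = 0.5, ratio = 0.8,
                           mode = c("strict", "paper_faithful"), seed = 0L) {
  mode <- match.arg(mode)
  if (is.null(maskTarget)) maskTarget <- (mode == "strict")
  cfg <- list(delta = delta, semSign = semSign, muPrime = muPrime,
              bandwidthRule = bandwidthRule, layout = layout,
              interactionBlocks = interactionBlocks, maskTarget = maskTarget,
              latentDim = as.integer(latentDim), epochs = as.integer(epochs),
              batchSize = as.integer(batchSize), aeLearningRate = aeLearningRate,
              depth = as.integer(depth), nTrees = as.integer(nTrees),
              learningRate = learningRate, threshold = threshold, ratio = ratio,
              mode = mode, seed = as.integer(seed))
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Compute all six similarity matrices
#'
#' Semantic matrices come from the hierarchy alone; functional and Gaussian
#' kernel matrices from the supplied interaction matrix (training fold in
#' strict mode).
#'
#' @param interaction an \linkS4class{InteractionMatrix}.
#' @param hierarchy a \linkS4class{DiseaseHierarchy}.
#' @param config a [pipelineConfig()].
#' @return named list with DISSS1, DISSS2, DISGS, LNCFS1, LNCFS2, LNCGS.
#' @export
computeSimilarityMatrices <- function(interaction, hierarchy, config = pipelineConfig()) {
  sem <- semanticSimilarityMatrices(diseaseNames(interaction), hierarchy,
                                    delta = config$delta, sign = config$semSign)
  list(DISSS1 = sem$DISSS1,
       DISSS2 = sem$DISSS2,
       DISGS = gipSimilarity(interaction, "diseases", config$muPrime, config$bandwidthRule),
       LNCFS1 = functionalSimilarity(interaction, sem$DISSS1),
       LNCFS2 = functionalSimilarity(interaction, sem$DISSS2),
       LNCGS = gipSimilarity(interaction, "lncrnas", config$muPrime, config$bandwidthRule))
}

#' Fit the full prediction pipeline on a training pair set
#'
#' Similarities -> per-pair features -> autoencoder -> gradient booster.
#' \code{sims} and \code{encoder} can be supplied to reuse precomputed
#' stages (paper-faithful mode); otherwise both are built from the training
#' interaction matrix and pairs.
#'
#' @param interaction training \linkS4class{InteractionMatrix} (test
#'   positives zeroed in strict mode).
#' @param hierarchy a \linkS4class{DiseaseHierarchy}.
#' @param trainPairs data.frame with \code{disease}, \code{lncRNA},
#'   \code{label}.
#' @param config a [pipelineConfig()].
#' @param sims,encoder optional precomputed similarity list / encoder.
#' @return a fitted pipeline model (list with the similarity matrices,
#'   encoder, booster and config).
#' @export
fitPipeline <- function(interaction, hierarchy, trainPairs,
                        config = pipelineConfig(), sims = NULL, encoder = NULL) {
  if (is.null(sims))
    sims <- computeSimilarityMatrices(interaction, hierarchy, config)
  fs <- assemblePairFeatures(trainPairs, config$layout, sims, interaction,
                             maskTarget = config$maskTarget,
                             interactionBlocks = config$interactionBlocks)
  if (is.null(encoder))
    encoder <- trainAutoencoder(pairFeatures(fs),
                                latentDim = min(config$latentDim, ncol(pairFeatures(fs))),
                                epochs = config$epochs, batchSize = config$batchSize,
                                learningRate = config$aeLearningRate,
                                seed = config$seed)
  Z <- encodeFeatures(encoder, pairFeatures(fs))
  gbm <- trainGradientBoosting(Z, pairLabels(fs), depth = config$depth,
                               nTrees = config$nTrees,
                               learningRate = config$learningRate,
                               seed = config$seed)
  structure(list(interaction = interaction, sims = sims, encoder = encoder,
                 gbm = gbm, config = config),
            class = "pipelineModel")
}

#' Score (disease, lncRNA) pairs with a fitted pipeline
#'
#' @param model a fitted pipeline from [fitPipeline()].
#' @param pairs data.frame with \code{disease}, \code{lncRNA} (a
#'   \code{label} column, if present, is ignored for scoring).
#' @return numeric association scores in (0, 1).
#' @export
scorePairs <- function(model, pairs) {
  cfg <- model$config
  if (is.null(pairs$label)) pairs$label <- 0L
  fs <- assemblePairFeatures(pairs, cfg$layout, model$sims, model$interaction,
                             maskTarget = cfg$maskTarget,
                             interactionBlocks = cfg$interactionBlocks)
  Z <- encodeFeatures(model$encoder, pairFeatures(fs))
  predictScore(model$gbm, Z)
}

#' Assemble an evaluation dataset
#'
#' Bundles the interaction matrix, hierarchy and a balanced labelled pair
#' set (all positives plus an equal number of sampled negatives).
#'
#' @param x an \linkS4class{InteractionMatrix} or
#'   \linkS4class{SyntheticBundle}.
#' @param hierarchy a \linkS4class{DiseaseHierarchy} (taken from the bundle
#'   when \code{x} is one).
#' @param nNegatives negatives to sample (default: the positive count).
#' @param seed seed of the negative draw.
#' @return list with \code{interaction}, \code{hierarchy}, \code{pairs}.
#' @export
buildDataset <- function(x, hierarchy = NULL, nNegatives = NULL, seed = 0) {
  if (is(x, "SyntheticBundle")) {
    hierarchy <- x@hierarchy
    x <- x@interaction
  }
  stopifnot2(is(x, "InteractionMatrix") && is(hierarchy, "DiseaseHierarchy"),
             "need an InteractionMatrix and a DiseaseHierarchy")
  list(interaction = x, hierarchy = hierarchy,
       pairs = labeledPairSet(x, nNegatives, seed))
}

# zero the cells of the given positive pairs out of the interaction matrix
# (strict-mode training matrix: held-out associations are unknown)
maskInteraction <- function(interaction, pairs) {
  m <- as.matrix(interaction)
  pos <- pairs[pairs$label == 1L, , drop = FALSE]
  if (nrow(pos)) m[cbind(pos$disease, pos$lncRNA)] <- 0
  new("InteractionMatrix", assoc = m)
}

# fit on trainPairs / score testPairs under the config's leakage mode;
# precomp (sims + encoder from the full data) is reused in paper-faithful mode
fitAndScore <- function(dataset, trainPairs, testPairs, config, precomp = NULL) {
  if (config$mode == "strict") {
    trainInt <- maskInteraction(dataset$interaction, testPairs)
    model <- fitPipeline(trainInt, dataset$hierarchy, trainPairs, config)
  } else {
    model <- fitPipeline(dataset$interaction, dataset$hierarchy, trainPairs, config,
                         sims = precomp$sims, encoder = precomp$encoder)
  }
  scorePairs(model, testPairs)
}

# precompute full-data similarities and encoder for paper-faithful protocols
precomputeFull <- function(dataset, config) {
  if (config$mode != "paper_faithful") return(NULL)
  sims <- computeSimilarityMatrices(dataset$interaction, dataset$hierarchy, config)
  fs <- assemblePairFeatures(dataset$pairs, config$layout, sims, dataset$interaction,
                             maskTarget = config$maskTarget,
                             interactionBlocks = config$interactionBlocks)
  encoder <- trainAutoencoder(pairFeatures(fs),
                              latentDim = min(config$latentDim, ncol(pairFeatures(fs))),
                              epochs = config$epochs, batchSize = config$batchSize,
                              learningRate = config$aeLearningRate, seed = config$seed)
  list(sims = sims, encoder = encoder)
}
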