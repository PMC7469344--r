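#' Confusion counts at a score threshold
#'
#' @param labels binary 0/1 labels.
#' @param scores numeric scores.
#' @param threshold classification threshold, default 0.5 (scores above are
#'   called positive).
#' @return list with integer \code{TP}, \code{FP}, \code{TN}, \code{FN}.
#' @export
confusionCounts <- function(labels, scores, threshold = 0.5) {
  stopifnot2(length(labels) == length(scores), "labels and scores must align")
  pred <- as.integer(scores >= threshold)
  list(TP = sum(pred == 1 & labels == 1), FP = sum(pred == 1 & labels == 0),
       TN = sum(pred == 0 & labels == 0), FN = sum(pred == 0 & labels == 1))
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity, precision and the Matthews
#' correlation coefficient. Metrics with a zero marginal (e.g. precision
#' with no positive calls) are reported as 0 and listed under
#' \code{degenerate}.
#'
#' @param counts list with \code{TP}, \code{FP}, \code{TN}, \code{FN}.
#' @return list with \code{Acc}, \code{Sen}, \code{Spe}, \code{Pre},
#'   \code{MCC}, \code{F1}, the counts, and \code{degenerate}.
#' @export
confusionMetrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  total <- TP + FP + TN + FN
  stopifnot2(total > 0, "empty confusion counts")
  degenerate <- character()
  sdiv <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); 0 } else num / den
  }
  acc <- (TP + TN) / total
  sen <- sdiv(TP, TP + FN, "Sen")
  spe <- sdiv(TN, TN + FP, "Spe")
  pre <- sdiv(TP, TP + FP, "Pre")
  mccDen <- (TP + FN) * (TP + FP) * (TN + FN) * (TN + FP)
  mcc <- if (mccDen == 0) { degenerate <- c(degenerate, "MCC"); 0 } else
    (TP * TN - FP * FN) / sqrt(mccDen)
  f1 <- if (pre + sen == 0) { degenerate <- c(degenerate, "F1"); 0 } else
    2 * pre * sen / (pre + sen)
  list(Acc = acc, Sen = sen, Spe = spe, Pre = pre, MCC = mcc, F1 = f1,
       counts = counts, degenerate = degenerate)
}

#' ROC curve and AUC
#'
#' Points are computed by sweeping the score thresholds with ties grouped,
#' so the trapezoidal area equals the Mann-Whitney probability that a random
#' positive outscores a random negative (ties counting one half).
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels, both classes present.
#' @return list with \code{fpr}, \code{tpr} (monotone point coordinates,
#'   from (0,0) to (1,1)) and \code{auc}.
#' @export
rocCurve <- function(scores, labels) {
  stopifnot2(length(unique(labels)) == 2, "both classes required for a ROC curve")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores: one curve point per distinct threshold
  tpCum <- cumsum(y); fpCum <- cumsum(1 - y)
  lastIdx <- which(c(s[-1] != s[-length(s)], TRUE))
  tpr <- c(0, tpCum[lastIdx] / n1)
  fpr <- c(0, fpCum[lastIdx] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

# Mann-Whitney AUC via mean ranks (ties count 1/2); equals the trapezoid
aucRank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# full report for one scored test set
metricReport <- function(labels, scores, threshold = 0.5, protocol = "holdout",
                         seed = NA_integer_) {
  rep <- confusionMetrics(confusionCounts(labels, scores, threshold))
  rep$auc <- rocCurve(scores, labels)$auc
  rep$protocol <- protocol
  rep$seed <- seed
  rep$scores <- scores
  rep$labels <- labels
  rep
}

# stratified index split: returns logical test mask with a testFraction of
# each class (rounded), reproducible under seed
stratifiedTestMask <- function(labels, testFraction, seed) {
  mask <- logical(length(labels))
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      nTest <- round(length(idx) * testFraction)
      stopifnot2(nTest >= 1 && nTest < length(idx),
                 "too few samples in a class to split")
      mask[sample(idx, nTest)] <- TRUE
    }
  })
  mask
}

#' Hold-out evaluation of the full pipeline
#'
#' Stratified random split (80/20 by default), pipeline trained on the
#' training part and scored on the held-out part. In strict mode the
#' held-out positives are removed from the interaction matrix before any
#' similarity is computed.
#'
#' @param dataset a dataset from [buildDataset()].
#' @param config a [pipelineConfig()].
#' @param ratio training fraction (default from config).
#' @param seed split seed (default from config).
#' @return metric report list (metrics, counts, auc, pooled scores/labels).
#' @export
holdoutEval <- function(dataset, config = pipelineConfig(), ratio = config$ratio,
                        seed = config$seed) {
  test <- stratifiedTestMask(dataset$pairs$label, 1 - ratio, seed)
  trainPairs <- dataset$pairs[!test, , drop = FALSE]
  testPairs <- dataset$pairs[test, , drop = FALSE]
  precomp <- precomputeFull(dataset, config)
  scores <- fitAndScore(dataset, trainPairs, testPairs, config, precomp)
  metricReport(testPairs$label, scores, config$threshold, "holdout", seed)
}

#' k-fold cross-validation of the full pipeline
#'
#' Stratified disjoint folds; one report per fold plus the arithmetic mean
#' of the fold metrics and the pooled held-out scores.
#'
#' @param dataset a dataset from [buildDataset()].
#' @param config a [pipelineConfig()].
#' @param k number of folds, default 10.
#' @param seed fold-assignment seed (default from config).
#' @return list with \code{folds} (per-fold reports), \code{mean} (named
#'   metric means incl. \code{auc}), \code{pooled} (scores, labels).
#' @export
kfoldEval <- function(dataset, config = pipelineConfig(), k = 10, seed = config$seed) {
  labels <- dataset$pairs$label
  stopifnot2(k >= 2 && k <= length(labels), "k must lie in [2, n]")
  foldId <- integer(length(labels))
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      foldId[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  precomp <- precomputeFull(dataset, config)
  folds <- lapply(seq_len(k), function(f) {
    trainPairs <- dataset$pairs[foldId != f, , drop = FALSE]
    testPairs <- dataset$pairs[foldId == f, , drop = FALSE]
    scores <- fitAndScore(dataset, trainPairs, testPairs, config, precomp)
    metricReport(testPairs$label, scores, config$threshold,
                 sprintf("fold%d/%d", f, k), seed)
  })
  metricNames <- c("Acc", "Sen", "Spe", "Pre", "MCC", "F1", "auc")
  means <- vapply(metricNames, function(nm)
    mean(vapply(folds, function(r) r[[nm]], numeric(1))), numeric(1))
  list(folds = folds, mean = means,
       pooled = list(scores = unlist(lapply(folds, `[[`, "scores")),
                     labels = unlist(lapply(folds, `[[`, "labels")),
                     foldId = foldId))
}

#' Leave-one-out cross-validation
#'
#' One held-out score per pair; AUC and confusion metrics are computed on
#' the pooled scores (a single left-out sample has no per-fold AUC).
#'
#' @param dataset a dataset from [buildDataset()].
#' @param config a [pipelineConfig()].
#' @return metric report on the pooled scores.
#' @export
loocvEval <- function(dataset, config = pipelineConfig()) {
  n <- nrow(dataset$pairs)
  stopifnot2(n >= 10, "LOOCV needs at least 10 pairs")
  precomp <- precomputeFull(dataset, config)
  scores <- vapply(seq_len(n), function(i) {
    fitAndScore(dataset, dataset$pairs[-i, , drop = FALSE],
                dataset$pairs[i, , drop = FALSE], config, precomp)
  }, numeric(1))
  metricReport(dataset$pairs$label, scores, config$threshold, "loocv", config$seed)
}

#' Paired repeated hold-out F1 comparison (t-test)
#'
#' Repeats the hold-out protocol with distinct split seeds for two pipeline
#' configurations and compares the F1 distributions with a two-sample
#' t-test. Zero variance in both arms (e.g. identical configurations) is
#' flagged instead of producing a spurious p-value.
#'
#' @param dataset a dataset from [buildDataset()].
#' @param configA,configB the two [pipelineConfig()]s.
#' @param nRep repetitions, default 20 (fewer than 5 warns about power).
#' @param seed base seed; repetition r uses \code{seed + r}.
#' @return list with per-arm F1 vectors, means, sds and \code{pValue}.
#' @export
repeatedF1Test <- function(dataset, configA, configB, nRep = 20, seed = 0) {
  if (nRep < 5) warning("low power: fewer than 5 repetitions")
  f1 <- function(cfg) vapply(seq_len(nRep), function(r)
    holdoutEval(dataset, cfg, seed = seed + r)$F1, numeric(1))
  f1A <- f1(configA); f1B <- f1(configB)
  zeroVar <- stats::sd(f1A - f1B) == 0
  p <- if (zeroVar) NA_real_ else stats::t.test(f1A, f1B)$p.value
  list(f1A = f1A, f1B = f1B,
       meanA = mean(f1A), sdA = stats::sd(f1A),
       meanB = mean(f1B), sdB = stats::sd(f1B),
       pValue = p, zeroVariance = zeroVar)
}

#' Rank candidate lncRNAs for a query disease
#'
#' Removes every known association of the query disease from the training
#' positives (and, in strict mode, from the interaction matrix), trains the
#' pipeline on the remainder plus sampled negatives, then scores all lncRNAs
#' paired with the query disease and returns them in descending score order.
#' Ties are broken by lncRNA index.
#'
#' @param disease disease name or row index.
#' @param dataset a dataset from [buildDataset()].
#' @param config a [pipelineConfig()].
#' @return data.frame with \code{lncRNA}, \code{index}, \code{score},
#'   \code{rank}.
#' @export
rankCandidates <- function(disease, dataset, config = pipelineConfig()) {
  dn <- diseaseNames(dataset$interaction)
  di <- if (is.character(disease)) match(disease, dn) else as.integer(disease)
  stopifnot2(!is.na(di) && di >= 1 && di <= length(dn),
             paste("unknown disease:", disease))
  nl <- length(lncRNANames(dataset$interaction))

  queryPairs <- data.frame(disease = di,
                           lncRNA = seq_len(nl),
                           label = as.integer(as.matrix(dataset$interaction)[di, ]))
  trainPairs <- dataset$pairs[dataset$pairs$disease != di, , drop = FALSE]
  stopifnot2(sum(trainPairs$label) > 0, "no training positives left")

  if (config$mode == "strict") {
    trainInt <- maskInteraction(dataset$interaction,
                                data.frame(disease = di, lncRNA = seq_len(nl),
                                           label = 1L))
    model <- fitPipeline(trainInt, dataset$hierarchy, trainPairs, config)
  } else {
    precomp <- precomputeFull(dataset, config)
    model <- fitPipeline(dataset$interaction, dataset$hierarchy, trainPairs, config,
                         sims = precomp$sims, encoder = precomp$encoder)
  }
  scores <- scorePairs(model, queryPairs)
  ord <- order(-scores, seq_len(nl))
  data.frame(lncRNA = lncRNANames(dataset$interaction)[ord], index = ord,
             score = scores[ord], rank = seq_len(nl), row.names = NULL)
}
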