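#' Train gradient boosted regression trees (binomial deviance)
#'
#' Friedman-style gradient boosting for binary labels: the initial score is
#' the log-odds of the positive rate; each iteration fits a depth-bounded
#' least-squares regression tree to the negative gradient of the binomial
#' deviance (the residuals y - p) and replaces each leaf value by the
#' one-step Newton estimate sum(r) / sum(p (1 - p)) over the leaf, shrunk by
#' the learning rate. No row or feature subsampling is used, and the split
#' search breaks ties deterministically (lowest feature index, then lowest
#' threshold), so training is bit-reproducible; the seed is recorded for
#' provenance only.
#'
#' @param X numeric feature matrix.
#' @param y binary 0/1 labels (both classes required).
#' @param depth maximum tree depth, default 3.
#' @param nTrees number of trees, default 1200.
#' @param learningRate shrinkage eta in (0, 1], plus the eta = 0 edge case
#'   (no updates; constant base-rate model).
#' @param seed recorded seed, default 0.
#' @return a \linkS4class{BoostedModel} with the training deviance after
#'   each tree in \code{lossTrace}.
#' @export
trainGradientBoosting <- function(X, y, depth = 3L, nTrees = 1200L,
                                  learningRate = 0.1, seed = 0L) {
  stopifnot2(is.matrix(X) && all(is.finite(X)), "X must be a finite numeric matrix")
  y <- as.numeric(y)
  stopifnot2(length(y) == nrow(X) && all(y %in% c(0, 1)), "y must be 0/1 per row")
  stopifnot2(length(unique(y)) == 2, "both classes must be present")
  stopifnot2(depth >= 1 && nTrees >= 1, "depth and nTrees must be >= 1")
  stopifnot2(learningRate >= 0 && learningRate <= 1, "learningRate must be in [0, 1]")

  pbar <- mean(y)
  f0 <- log(pbar / (1 - pbar))
  F <- rep(f0, nrow(X))
  trees <- vector("list", nTrees)
  trace <- numeric(nTrees)
  for (m in seq_len(nTrees)) {
    p <- sigmoid(F)
    r <- y - p
    tree <- .fitRegTree(X, r, max_depth = as.integer(depth))
    # per-leaf Newton step on the deviance
    w <- p * (1 - p)
    leaves <- tree$leaf_of + 1L
    num <- tapply(r, leaves, sum)
    den <- tapply(w, leaves, sum)
    gamma <- num / pmax(den, 1e-12)
    tree$value[as.integer(names(gamma))] <- as.numeric(gamma)
    tree$leaf_of <- NULL
    trees[[m]] <- tree
    F <- F + learningRate * .predictRegTree(tree, X)
    pnew <- sigmoid(F)
    eps <- 1e-15
    trace[m] <- -mean(y * log(pmax(pnew, eps)) + (1 - y) * log(pmax(1 - pnew, eps)))
  }
  new("BoostedModel", f0 = f0, trees = trees, learningRate = learningRate,
      lossTrace = trace, nFeatures = ncol(X), seed = as.integer(seed))
}

#' Predict association probabilities
#'
#' Logistic transform of the additive raw score
#' \code{F0 + eta * sum_m gamma_m(x)}.
#'
#' @param model a \linkS4class{BoostedModel}.
#' @param X feature matrix with the training dimension.
#' @return scores in (0, 1).
#' @export
predictScore <- function(model, X) {
  stopifnot2(ncol(X) == model@nFeatures,
             sprintf("input has %d columns, model expects %d", ncol(X), model@nFeatures))
  F <- rep(model@f0, nrow(X))
  for (tree in model@trees)
    F <- F + model@learningRate * .predictRegTree(tree, X)
  sigmoid(F)
}

#' Per-iteration training loss
#'
#' The binomial deviance on the training data after each fitted tree;
#' non-increasing up to numerical tolerance.
#'
#' @param model a trained \linkS4class{BoostedModel}.
#' @return numeric vector, one value per tree.
#' @export
stagedTrainingLoss <- function(model) {
  stopifnot2(length(model@trees) > 0, "model has no trained trees")
  model@lossTrace
}

#' Serialize / restore a boosted model
#'
#' Trees are stored as nested split records in JSON with 17-significant-digit
#' reals (exact double round-trip).
#'
#' @param model a \linkS4class{BoostedModel}.
#' @param path output file.
#' @return \code{readBoostedModel} returns the restored model.
#' @export
writeBoostedModel <- function(model, path) {
  obj <- list(f0 = .num17(model@f0), learningRate = .num17(model@learningRate),
              lossTrace = .num17(model@lossTrace), nFeatures = model@nFeatures,
              seed = model@seed,
              trees = lapply(model@trees, function(t)
                list(feature = t$feature, threshold = .num17(t$threshold),
                     left = t$left, right = t$right, value = .num17(t$value),
                     n = t$n)))
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeBoostedModel
#' @export
readBoostedModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) suppressWarnings(as.numeric(unlist(x)))  # "NA" thresholds on leaves
  int <- function(x) as.integer(unlist(x))
  trees <- lapply(obj$trees, function(t)
    list(feature = int(t$feature), threshold = num(t$threshold),
         left = int(t$left), right = int(t$right),
         value = num(t$value), n = int(t$n)))
  obj$f0 <- num(obj$f0); obj$learningRate <- num(obj$learningRate)
  obj$lossTrace <- num(obj$lossTrace)
  obj$nFeatures <- int(obj$nFeatures); obj$seed <- int(obj$seed)
  new("BoostedModel", f0 = as.numeric(obj$f0),
      trees = trees, learningRate = as.numeric(obj$learningRate),
      lossTrace = as.numeric(obj$lossTrace),
      nFeatures = as.integer(obj$nFeatures), seed = as.integer(obj$seed))
}
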