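#' Train a single hidden-layer sigmoid autoencoder
#'
#' Encoder and decoder are both sigmoid layers; training minimises the
#' element-wise cross-entropy between the min-max scaled input and its
#' reconstruction by mini-batch gradient descent. The per-column min-max
#' scaler is fitted here and stored with the model, since the cross-entropy
#' loss requires inputs in [0, 1]. Training is deterministic for a fixed
#' seed (seeded uniform weight initialisation in [-0.05, 0.05] and seeded
#' batch shuffling).
#'
#' @param X numeric matrix of training rows (any scale; min-max scaled
#'   internally).
#' @param latentDim encoded dimensionality (default 128, capped at the input
#'   dimension).
#' @param epochs training epochs, default 100.
#' @param batchSize mini-batch size, default 128.
#' @param learningRate gradient step size on the per-element mean gradient.
#' @param seed RNG seed.
#' @return an \linkS4class{EncoderModel} with one loss value per epoch.
#' @export
trainAutoencoder <- function(X, latentDim = 128L, epochs = 100L, batchSize = 128L,
                             learningRate = 1, seed = 0) {
  stopifnot2(is.matrix(X) && all(is.finite(X)), "X must be a finite numeric matrix")
  stopifnot2(epochs >= 1, "epochs must be >= 1")
  latentDim <- as.integer(latentDim)
  stopifnot2(latentDim >= 1 && latentDim <= ncol(X),
             "latentDim must lie in [1, input dimension]")
  n <- nrow(X); p <- ncol(X)

  scaleMin <- apply(X, 2, min)
  scaleRange <- apply(X, 2, max) - scaleMin
  scaleRange[scaleRange == 0] <- 1   # constant columns map to 0
  Xs <- sweep(sweep(X, 2, scaleMin), 2, scaleRange, "/")

  withSeed(seed, {
    W1 <- matrix(stats::runif(p * latentDim, -0.05, 0.05), p, latentDim)
    b1 <- stats::runif(latentDim, -0.05, 0.05)
    W2 <- matrix(stats::runif(latentDim * p, -0.05, 0.05), latentDim, p)
    b2 <- stats::runif(p, -0.05, 0.05)
    trace <- numeric(epochs)
    eps <- 1e-12
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1, n)]
        xb <- Xs[idx, , drop = FALSE]
        h <- sigmoid(sweep(xb %*% W1, 2, b1, "+"))
        xhat <- sigmoid(sweep(h %*% W2, 2, b2, "+"))
        # cross-entropy + sigmoid output: output delta is (xhat - x);
        # gradients averaged over the batch (summed over feature columns)
        dout <- (xhat - xb) / length(idx)
        dh <- (dout %*% t(W2)) * h * (1 - h)
        W2 <- W2 - learningRate * crossprod(h, dout)
        b2 <- b2 - learningRate * colSums(dout)
        W1 <- W1 - learningRate * crossprod(xb, dh)
        b1 <- b1 - learningRate * colSums(dh)
      }
      h <- sigmoid(sweep(Xs %*% W1, 2, b1, "+"))
      xhat <- sigmoid(sweep(h %*% W2, 2, b2, "+"))
      trace[e] <- -mean(Xs * log(xhat + eps) + (1 - Xs) * log(1 - xhat + eps))
    }
  })
  new("EncoderModel", W1 = W1, b1 = b1, W2 = W2, b2 = b2,
      latentDim = latentDim, lossTrace = trace,
      scaleMin = scaleMin, scaleRange = scaleRange)
}

#' Encode feature rows
#'
#' Applies the model's stored min-max scaler (clipping to [0, 1] for values
#' outside the training range) and the sigmoid encoder layer.
#'
#' @param model an \linkS4class{EncoderModel}.
#' @param X matrix with the model's input dimension.
#' @return matrix of encoded rows, entries in (0, 1).
#' @export
encodeFeatures <- function(model, X) {
  stopifnot2(ncol(X) == nrow(model@W1),
             sprintf("input has %d columns, model expects %d", ncol(X), nrow(model@W1)))
  Xs <- sweep(sweep(X, 2, model@scaleMin), 2, model@scaleRange, "/")
  Xs[Xs < 0] <- 0; Xs[Xs > 1] <- 1
  sigmoid(sweep(Xs %*% model@W1, 2, model@b1, "+"))
}

#' Reconstruct inputs through the autoencoder
#'
#' @param model an \linkS4class{EncoderModel}.
#' @param X matrix with the model's input dimension.
#' @return reconstruction on the scaled [0, 1] scale.
#' @export
reconstructFeatures <- function(model, X) {
  h <- encodeFeatures(model, X)
  sigmoid(sweep(h %*% model@W2, 2, model@b2, "+"))
}

#' Serialize / restore an encoder model
#'
#' Plain-text JSON bundle; matrices are stored as value lists printed with 17
#' significant digits so the round-trip is exact for doubles.
#'
#' @param model an \linkS4class{EncoderModel}.
#' @param path output file.
#' @return \code{readEncoderModel} returns the restored
#'   \linkS4class{EncoderModel}.
#' @export
writeEncoderModel <- function(model, path) {
  obj <- list(W1 = .num17(model@W1), dimW1 = dim(model@W1), b1 = .num17(model@b1),
              W2 = .num17(model@W2), dimW2 = dim(model@W2), b2 = .num17(model@b2),
              latentDim = model@latentDim, lossTrace = .num17(model@lossTrace),
              scaleMin = .num17(model@scaleMin), scaleRange = .num17(model@scaleRange))
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeEncoderModel
#' @export
readEncoderModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("EncoderModel",
      W1 = matrix(as.numeric(obj$W1), obj$dimW1[1], obj$dimW1[2]),
      b1 = as.numeric(obj$b1),
      W2 = matrix(as.numeric(obj$W2), obj$dimW2[1], obj$dimW2[2]),
      b2 = as.numeric(obj$b2),
      latentDim = as.integer(obj$latentDim),
      lossTrace = as.numeric(obj$lossTrace),
      scaleMin = as.numeric(obj$scaleMin),
      scaleRange = as.numeric(obj$scaleRange))
}

# print doubles with 17 significant digits (exact binary round-trip)
.num17 <- function(x) sprintf("%.17g", as.vector(x))
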