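# Fully connected autoencoder, trained by backpropagation with Adam. Cohorts
# are tiny (tens of subjects), so training is full-batch and runs in seconds
# even on 64,620-dimensional inputs; implemented directly on matrix algebra,
# no deep-learning framework needed.

#' Autoencoder configuration
#'
#' Symmetric fully connected architecture: encoder `input -> hiddenDims...
#' -> latentDim`, decoder mirrored. ReLU on hidden layers, linear latent and
#' output, mean squared reconstruction error, Adam optimizer, full-batch
#' training.
#'
#' @param hiddenDims encoder hidden layer widths, strictly decreasing.
#' @param latentDim latent dimension; must be below the input dimension.
#' @param epochs training epochs.
#' @param learningRate Adam step size. The default is deliberately
#'   conservative: at cohort sizes of a few dozen subjects an over-trained
#'   autoencoder memorizes individual subjects and distorts latent
#'   distances, degrading the clustering geometry; the slow rate keeps the
#'   encoder in the regime where it captures shared structure.
#' @param seed integer seed for weight initialization (training itself is
#'   deterministic given the initialization).
#' @return A list of class `"AutoencoderConfig"`.
#' @export
autoencoderConfig <- function(hiddenDims = c(256, 64), latentDim = 16,
                              epochs = 200, learningRate = 1e-4,
                              seed = 1L) {
  if (length(hiddenDims) && any(diff(c(hiddenDims, latentDim)) >= 0))
    fcStop("bad_argument",
           "hiddenDims must decrease strictly toward latentDim")
  structure(list(hiddenDims = as.integer(hiddenDims),
                 latentDim = as.integer(latentDim),
                 epochs = as.integer(epochs),
                 learningRate = learningRate, seed = as.integer(seed)),
            class = "AutoencoderConfig")
}

relu <- function(x) pmax(x, 0)

aeForward <- function(X, W, b, linearIdx) {
  A <- vector("list", length(W) + 1L)
  A[[1]] <- X
  for (l in seq_along(W)) {
    Z <- A[[l]] %*% W[[l]]
    Z <- sweep(Z, 2L, b[[l]], "+")
    A[[l + 1L]] <- if (l %in% linearIdx) Z else relu(Z)
  }
  A
}

#' Train the autoencoder
#'
#' Standardizes features (per-dimension zero mean, unit variance across
#' subjects; constant features map to zero), trains the autoencoder on the
#' standardized matrix, and returns the latent embedding of every training
#' subject together with the per-epoch loss trace.
#'
#' @param X numeric matrix, subjects x features (e.g. `t(fcMatrix(fce))`).
#' @param cfg an [autoencoderConfig()].
#' @param standardize standardize features before training (recommended:
#'   otherwise the reconstruction loss is dominated by high-variance edges).
#' @return List of class `"Autoencoder"` with elements `embedding`
#'   (subjects x latentDim, rownames preserved), `losses` (per-epoch MSE),
#'   `finalTrainLoss`, the weights, and the standardization constants.
#' @export
trainAutoencoder <- function(X, cfg = autoencoderConfig(),
                             standardize = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) fcStop("bad_argument", "need at least 2 subjects")
  if (!all(is.finite(X))) fcStop("bad_argument", "inputs must be finite")
  if (cfg$latentDim >= ncol(X))
    fcStop("bad_argument", "latentDim must be below the input dimension")
  center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[scale == 0] <- 1
  }
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")

  sizes <- c(ncol(X), cfg$hiddenDims, cfg$latentDim,
             rev(cfg$hiddenDims), ncol(X))
  nl <- length(sizes) - 1L
  encDepth <- length(cfg$hiddenDims) + 1L
  linearIdx <- c(encDepth, nl)            # latent and output layers
  set.seed(cfg$seed)
  W <- vector("list", nl); b <- vector("list", nl)
  for (l in seq_len(nl)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  N <- nrow(Xs); D <- ncol(Xs)
  losses <- numeric(cfg$epochs)
  t0 <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    A <- aeForward(Xs, W, b, linearIdx)
    resid <- A[[nl + 1L]] - Xs
    loss <- mean(resid^2)
    if (!is.finite(loss))
      fcStop("diverged",
             "training loss is non-finite; reduce the learning rate")
    losses[epoch] <- loss
    delta <- 2 * resid / (N * D)
    t0 <- t0 + 1L
    for (l in rev(seq_len(nl))) {
      dW <- crossprod(A[[l]], delta)
      db <- colSums(delta)
      if (l > 1L) {
        delta <- delta %*% t(W[[l]])
        if (!((l - 1L) %in% linearIdx)) delta <- delta * (A[[l]] > 0)
      }
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * dW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * dW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * db
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * db^2
      lr <- cfg$learningRate * sqrt(1 - beta2^t0) / (1 - beta1^t0)
      W[[l]] <- W[[l]] - lr * mW[[l]] / (sqrt(vW[[l]]) + eps)
      b[[l]] <- b[[l]] - lr * mb[[l]] / (sqrt(vb[[l]]) + eps)
    }
  }
  model <- structure(list(W = W, b = b, cfg = cfg, center = center,
                          scale = scale, encDepth = encDepth,
                          linearIdx = linearIdx, losses = losses,
                          finalTrainLoss = losses[cfg$epochs]),
                     class = "Autoencoder")
  model$embedding <- encode(model, X, standardized = FALSE)
  fcLog("autoencoder", sprintf(
    "%d x %d -> latent %d; %d epochs; final MSE %.5g; seed %d",
    N, D, cfg$latentDim, cfg$epochs, model$finalTrainLoss, cfg$seed))
  model
}

#' Encode subjects into the latent space
#'
#' @param model a trained `"Autoencoder"`.
#' @param X subjects x features matrix on the original (raw) scale.
#' @param standardized set `TRUE` if `X` is already standardized.
#' @return Subjects x latentDim matrix.
#' @export
encode <- function(model, X, standardized = FALSE) {
  X <- as.matrix(X)
  if (!standardized)
    X <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  A <- aeForward(X, model$W[seq_len(model$encDepth)],
                 model$b[seq_len(model$encDepth)],
                 linearIdx = model$encDepth)
  z <- A[[model$encDepth + 1L]]
  rownames(z) <- rownames(X)
  z
}

#' Principal-component embedding
#'
#' Linear fallback for the autoencoder: top principal components of the
#' (optionally standardized) feature matrix. Useful as a sanity check that
#' subtype recovery does not depend on autoencoder quirks.
#'
#' @param X subjects x features matrix.
#' @param dim number of components.
#' @param standardize standardize features first.
#' @return Subjects x `dim` score matrix.
#' @export
pcaEmbedding <- function(X, dim = 16, standardize = TRUE) {
  X <- as.matrix(X)
  if (standardize) {
    s <- apply(X, 2L, stats::sd)
    X <- sweep(X, 2L, colMeans(X))
    X[, s > 0] <- sweep(X[, s > 0, drop = FALSE], 2L, s[s > 0], "/")
  }
  dim <- min(dim, nrow(X) - 1L, ncol(X))
  p <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  z <- p$x[, seq_len(dim), drop = FALSE]
  rownames(z) <- rownames(X)
  z
}
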