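#' Pearson connectome from region time series
#'
#' Computes the sample Pearson correlation between every pair of rows of a
#' region-by-time matrix. A region whose series has zero variance is a hard
#' error (naming the region) rather than a silently imputed zero, since
#' silent zeros distort downstream clustering features.
#'
#' @param ts numeric matrix, one row per region, rownames = region labels.
#' @param fisherZ apply the Fisher z-transform to off-diagonal entries.
#'   Defaults off: downstream intra-network summaries average raw `|r|`.
#' @return Symmetric correlation matrix with unit diagonal and the input's
#'   rownames as dimnames.
#' @export
#' @examples
#' ts <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("r", 1:4), NULL))
#' correlationMatrix(ts)
correlationMatrix <- function(ts, fisherZ = FALSE) {
  if (!is.matrix(ts) || !is.numeric(ts))
    fcStop("bad_argument", "'ts' must be a numeric matrix")
  if (ncol(ts) < 3L)
    fcStop("bad_argument", "need at least 3 timepoints")
  sds <- apply(ts, 1L, stats::sd)
  if (any(sds == 0)) {
    labs <- rownames(ts)
    bad <- if (is.null(labs)) which(sds == 0) else labs[sds == 0]
    fcStop("zero_variance",
           "constant (zero-variance) series for region(s): %s",
           paste(bad, collapse = ", "))
  }
  r <- stats::cor(t(ts))
  r <- (r + t(r)) / 2          # enforce exact symmetry
  diag(r) <- 1
  if (fisherZ) {
    z <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
    diag(z) <- 0
    dimnames(z) <- dimnames(r)
    return(z)
  }
  r
}

#' Vectorize the strict upper triangle
#'
#' Flattens a symmetric matrix into the row-major sequence of its strict
#' upper-triangle entries: (1,2), (1,3), ..., (1,n), (2,3), ... This fixed
#' ordering makes vectorize/devectorize exact inverses; clustering itself is
#' invariant to the convention.
#'
#' @param m square symmetric numeric matrix.
#' @return Numeric vector of length `n(n-1)/2`.
#' @seealso [devectorize()]
#' @export
vectorizeUpper <- function(m) {
  assertSquareSymmetric(m, tol = 1e-10, name = "m")
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' Rebuild a symmetric matrix from an upper-triangle vector
#'
#' Inverse of [vectorizeUpper()]: the vector is laid out row-major over pairs
#' i < j and mirrored; the diagonal is filled with `diagonalFill`.
#'
#' @param v numeric vector whose length is a triangular number `n(n-1)/2`.
#' @param diagonalFill value placed on the diagonal (1 for correlation
#'   matrices).
#' @return Symmetric `n x n` matrix.
#' @export
#' @examples
#' devectorize(c(0.1, 0.2, 0.3), diagonalFill = 1)
devectorize <- function(v, diagonalFill = 1) {
  m <- length(v)
  n <- (1 + sqrt(1 + 8 * m)) / 2
  if (abs(n - round(n)) > 1e-9)
    fcStop("not_triangular",
           "vector length %d is not a triangular number n(n-1)/2", m)
  n <- as.integer(round(n))
  out <- matrix(diagonalFill, n, n)
  tm <- matrix(0, n, n)
  tm[lower.tri(tm)] <- v      # row-major upper triangle of the transpose
  tm <- t(tm)
  out[upper.tri(out)] <- tm[upper.tri(tm)]
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Vectorized connectomes for a list of subjects
#'
#' Convenience constructor: computes each subject's Pearson connectome,
#' vectorizes the upper triangle and assembles an [FCExperiment-class].
#'
#' @param timeSeries named list of region-by-time matrices sharing row order.
#' @param colData subject metadata, one row per list element (in order).
#' @param parcellation optional [NetworkParcellation-class].
#' @return An [FCExperiment-class].
#' @export
buildFCExperiment <- function(timeSeries, colData, parcellation = NULL) {
  if (!length(timeSeries)) fcStop("bad_argument", "no subjects supplied")
  labs <- rownames(timeSeries[[1]])
  if (is.null(labs)) labs <- paste0("R", seq_len(nrow(timeSeries[[1]])))
  fc <- vapply(timeSeries,
               function(ts) vectorizeUpper(correlationMatrix(ts)),
               numeric(nrow(timeSeries[[1]]) *
                       (nrow(timeSeries[[1]]) - 1L) / 2L))
  colnames(fc) <- names(timeSeries)
  fcLog("connectome", sprintf("%d subjects, %d regions", ncol(fc),
                              length(labs)))
  FCExperiment(fc, colData = colData, regionLabels = labs,
               parcellation = parcellation)
}
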