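# Subject clustering in the latent space: Ward linkage over Euclidean
# distances, with the number of clusters chosen by joint Silhouette /
# Davies-Bouldin evaluation over a candidate range.

relabelBySize <- function(labels) {
  tab <- table(labels)
  ord <- names(tab)[order(-as.integer(tab), as.integer(names(tab)))]
  out <- match(as.character(labels), ord)
  stats::setNames(as.integer(out), names(labels))
}

#' Ward hierarchical clustering of a latent embedding
#'
#' Agglomerative clustering minimizing the Ward variance increase at each
#' merge (Euclidean distance, `stats::hclust(method = "ward.D2")`), cut at
#' `k` clusters. Labels are relabelled to descending cluster size, so
#' cluster 1 is always the largest.
#'
#' @param z subjects x dimensions numeric matrix (rownames = subject ids).
#' @param k number of clusters, `2 <= k <= nrow(z)`.
#' @return Named integer vector of cluster labels.
#' @export
wardCluster <- function(z, k) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (k < 2L || k > n)
    fcStop("bad_argument", "k = %d out of range [2, %d]", k, n)
  h <- stats::hclust(stats::dist(z), method = "ward.D2")
  labs <- stats::cutree(h, k = k)
  names(labs) <- rownames(z)
  relabelBySize(labs)
}

#' Internal clustering quality indices
#'
#' Definition-level implementations over Euclidean distances.
#' Silhouette: per point, `(b - a) / max(a, b)` with `a` the mean distance
#' to its own cluster and `b` the smallest mean distance to another cluster;
#' a point in a singleton cluster contributes 0 (convention), and identical
#' points (`max(a, b) = 0`) contribute 0. Davies-Bouldin: mean over clusters
#' of the largest `(s_i + s_j) / d_ij`, where `s` is the mean distance of a
#' cluster's points to its centroid and `d_ij` the centroid distance; two
#' coincident centroids with zero scatter contribute 0.
#'
#' @param z subjects x dimensions matrix.
#' @param labels integer cluster labels (>= 2 nonempty clusters).
#' @return Named numeric vector `c(silhouette =, davies_bouldin =)`.
#' @export
clusteringQuality <- function(z, labels) {
  z <- as.matrix(z)
  labels <- as.integer(labels)
  cl <- sort(unique(labels))
  if (length(cl) < 2L)
    fcStop("bad_argument", "need at least 2 clusters")
  n <- nrow(z)
  D <- as.matrix(stats::dist(z))

  sil <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { sil[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(cl[cl != labels[i]],
                    function(c) mean(D[i, labels == c]), numeric(1)))
    m <- max(a, b)
    sil[i] <- if (m == 0) 0 else (b - a) / m
  }

  cent <- t(vapply(cl, function(c)
    colMeans(z[labels == c, , drop = FALSE]), numeric(ncol(z))))
  scat <- vapply(seq_along(cl), function(ci) {
    pts <- z[labels == cl[ci], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2L, cent[ci, ])^2)))
  }, numeric(1))
  K <- length(cl)
  Rmax <- vapply(seq_len(K), function(i) {
    r <- vapply(setdiff(seq_len(K), i), function(j) {
      d <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      s <- scat[i] + scat[j]
      if (d == 0) { if (s == 0) 0 else Inf } else s / d
    }, numeric(1))
    max(r)
  }, numeric(1))

  c(silhouette = mean(sil), davies_bouldin = mean(Rmax))
}

#' Select the number of clusters
#'
#' Ward-clusters the embedding at every candidate `k`, computes both quality
#' indices, and selects the `k` with the highest silhouette, breaking ties
#' by lower Davies-Bouldin and then by smaller `k`. The full quality map is
#' returned so other joint rules (or a model-selection plot) can be applied.
#'
#' @param z subjects x dimensions matrix.
#' @param kRange candidate cluster counts (default 2:9); values above
#'   `nrow(z) - 1` are dropped.
#' @return List with `k` (selected), `labels` (named integer vector at the
#'   selected k), and `quality` (data.frame k, silhouette, davies_bouldin).
#' @export
selectK <- function(z, kRange = 2:9) {
  z <- as.matrix(z)
  kRange <- kRange[kRange >= 2L & kRange <= nrow(z) - 1L]
  if (!length(kRange))
    fcStop("bad_argument", "empty candidate k range")
  rows <- lapply(kRange, function(k) {
    labs <- wardCluster(z, k)
    q <- clusteringQuality(z, labs)
    list(k = k, labels = labs, silhouette = q[["silhouette"]],
         davies_bouldin = q[["davies_bouldin"]])
  })
  quality <- data.frame(
    k = vapply(rows, `[[`, numeric(1), "k"),
    silhouette = vapply(rows, `[[`, numeric(1), "silhouette"),
    davies_bouldin = vapply(rows, `[[`, numeric(1), "davies_bouldin"))
  best <- order(-quality$silhouette, quality$davies_bouldin, quality$k)[1]
  list(k = as.integer(quality$k[best]), labels = rows[[best]]$labels,
       quality = quality)
}

#' Subtype a cohort of connectomes
#'
#' The full subtype-discovery pipeline on an [FCExperiment-class]: restrict
#' to patients (every subject whose `group` is not `"CN"`), standardize the
#' upper-triangle FC features, compress them with the autoencoder (or PCA),
#' Ward-cluster the latent space for each candidate `k`, and select `k` by
#' the joint Silhouette / Davies-Bouldin rule.
#'
#' @param fce an [FCExperiment-class] with a `group` column in its colData.
#' @param kRange candidate cluster counts.
#' @param cfg an [autoencoderConfig()]; its seed controls all randomness.
#' @param embedding `"autoencoder"` (default) or `"pca"`.
#' @param patientsOnly cluster only non-CN subjects (default TRUE).
#' @return A [SubtypeClustering-class].
#' @export
subtypeCohort <- function(fce, kRange = 2:9, cfg = autoencoderConfig(),
                          embedding = c("autoencoder", "pca"),
                          patientsOnly = TRUE) {
  embedding <- match.arg(embedding)
  X <- t(fcMatrix(fce))
  if (patientsOnly) {
    grp <- colData(fce)$group
    if (is.null(grp))
      fcStop("bad_shape", "colData needs a 'group' column")
    X <- X[grp != "CN", , drop = FALSE]
  }
  fcLog("cluster", sprintf("%d subjects x %d features, embedding=%s, k=%s",
                           nrow(X), ncol(X), embedding,
                           paste(range(kRange), collapse = "..")))
  if (embedding == "autoencoder") {
    model <- trainAutoencoder(X, cfg)
    z <- model$embedding
    loss <- model$finalTrainLoss
  } else {
    z <- pcaEmbedding(X, dim = cfg$latentDim)
    loss <- NA_real_
  }
  sel <- selectK(z, kRange)
  new("SubtypeClustering", subjectIds = rownames(X),
      labels = as.integer(sel$labels), k = sel$k, quality = sel$quality,
      embedding = z, finalTrainLoss = loss)
}
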