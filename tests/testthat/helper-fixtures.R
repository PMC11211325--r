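# Shared fixtures and independent oracles. Everything is generated in code
# under fixed seeds; the default-spec cohort is built once and reused.

.fixtures <- new.env(parent = emptyenv())

sharedSim <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- suppressMessages(simulateCohort(CohortSpec(seed = 42L)))
  .fixtures$sim
}

sharedCohort <- function() {
  if (is.null(.fixtures$fce))
    .fixtures$fce <- suppressMessages(cohortToFCExperiment(sharedSim()))
  .fixtures$fce
}

randomSymmetricMatrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, -1, 1), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(paste0("R", seq_len(n)), paste0("R", seq_len(n)))
  m
}

randomAdjacency <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a <- a + t(a)
  dimnames(a) <- list(paste0("R", seq_len(n)), paste0("R", seq_len(n)))
  a
}

# independent all-pairs shortest-path oracle
floydWarshall <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

igraphFrom <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
}

# brute-force greedy Ward merges: at each step merge the pair of clusters
# minimizing the increase in total within-cluster sum of squares,
# |A||B|/(|A|+|B|) * ||cA - cB||^2, evaluated exhaustively over all pairs
wardOraclePartitions <- function(z) {
  n <- nrow(z)
  clusters <- lapply(seq_len(n), identity)
  partitions <- list()
  while (length(clusters) > 1L) {
    K <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      a <- z[clusters[[i]], , drop = FALSE]
      b <- z[clusters[[j]], , drop = FALSE]
      d2 <- sum((colMeans(a) - colMeans(b))^2)
      cost <- nrow(a) * nrow(b) / (nrow(a) + nrow(b)) * d2
      if (cost < best[1]) best <- c(cost, i, j)
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    labs <- integer(n)
    for (c in seq_along(clusters)) labs[clusters[[c]]] <- c
    partitions[[length(partitions) + 1L]] <- labs
  }
  partitions   # one per merge; element m has n - m clusters
}

# label-invariant partition equality
samePartition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# definition-level Davies-Bouldin, written as plain loops (oracle)
dbOracle <- function(z, labels) {
  cl <- sort(unique(labels))
  cent <- list(); scat <- numeric(length(cl))
  for (ci in seq_along(cl)) {
    pts <- z[labels == cl[ci], , drop = FALSE]
    cent[[ci]] <- colMeans(pts)
    s <- 0
    for (r in seq_len(nrow(pts)))
      s <- s + sqrt(sum((pts[r, ] - cent[[ci]])^2))
    scat[ci] <- s / nrow(pts)
  }
  total <- 0
  for (i in seq_along(cl)) {
    worst <- -Inf
    for (j in seq_along(cl)) {
      if (i == j) next
      d <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      worst <- max(worst, (scat[i] + scat[j]) / d)
    }
    total <- total + worst
  }
  total / length(cl)
}
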