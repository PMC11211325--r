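test_that("proportional thresholding keeps exactly the strongest edges", {
  m <- randomSymmetricMatrix(10, 51)

  empty <- thresholdAtPSW(m, 0)
  expect_true(all(empty$adjacency == 0))

  full <- thresholdAtPSW(m, 1)
  expect_true(all(full$adjacency[upper.tri(full$adjacency)] == 1))
  expect_equal(unname(diag(full$adjacency)), rep(0, 10))

  m4 <- devectorize(c(0.9, 0.1, 0.5, 0.8, 0.3, 0.6), diagonalFill = 1)
  g <- thresholdAtPSW(m4, 0.5)
  # exhaustive sort: top 3 of 6 weights are 0.9 (1,2), 0.8 (2,3), 0.6 (3,4)
  expect_equal(sum(g$adjacency) / 2, 3)
  expect_equal(g$adjacency[1, 2], 1)
  expect_equal(g$adjacency[2, 3], 1)
  expect_equal(g$adjacency[3, 4], 1)
  expect_equal(g$adjacency[1, 3], 0)
  expect_equal(g$retainedWeights[2, 3], 0.8)
})

test_that("edge count follows round(psw * n(n-1)/2) and ranks use |r|", {
  m <- randomSymmetricMatrix(12, 52)
  for (psw in c(0.1, 0.25, 0.33, 0.77)) {
    g <- thresholdAtPSW(m, psw)
    expect_equal(sum(g$adjacency) / 2, round(psw * 66))
    kept <- abs(m[g$adjacency == 1])
    droppedMask <- g$adjacency == 0 & upper.tri(m)
    if (any(droppedMask) && length(kept))
      expect_gte(min(kept), max(abs(m[droppedMask])))
  }
})

test_that("ties at the cutoff break by lexicographic edge order", {
  m <- matrix(0.5, 4, 4); diag(m) <- 1
  g <- thresholdAtPSW(m, 0.5)   # 3 of 6 identical weights
  expect_equal(sum(g$adjacency) / 2, 3)
  # row-major pairs (1,2), (1,3), (1,4) come first
  expect_equal(g$adjacency[1, 2], 1)
  expect_equal(g$adjacency[1, 3], 1)
  expect_equal(g$adjacency[1, 4], 1)
  expect_equal(g$adjacency[2, 3], 0)
})

test_that("global efficiency has its closed-form values", {
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  expect_equal(globalEfficiency(k5)$E, 1)
  expect_equal(globalEfficiency(matrix(0, 5, 5))$E, 0)

  # path graph on 4 nodes: distances enumerable by hand
  p4 <- matrix(0, 4, 4)
  p4[cbind(1:3, 2:4)] <- 1; p4 <- p4 + t(p4)
  eff <- globalEfficiency(p4)
  expect_equal(eff$Ei[1], (1 + 1 / 2 + 1 / 3) / 3, tolerance = 1e-12)
  expect_equal(eff$Ei[2], (1 + 1 + 1 / 2) / 3, tolerance = 1e-12)
  expect_equal(eff$E, mean(eff$Ei), tolerance = 1e-12)
})

test_that("BFS distances agree with Floyd-Warshall on random graphs", {
  for (seed in 1:10) {
    a <- randomAdjacency(12, 0.25, seed)
    expect_equal(bfsDistances(a), floydWarshall(a),
                 ignore_attr = TRUE)
  }
})

test_that("unreachable pairs contribute zero inverse distance", {
  a <- matrix(0, 5, 5)
  a[1, 2] <- a[2, 1] <- 1   # one edge, three isolated nodes
  eff <- globalEfficiency(a)
  expect_equal(eff$Ei[1], 1 / 4)
  expect_equal(eff$Ei[3], 0)
})

test_that("the GCE curve is well-formed and E is monotone in PSW", {
  m <- randomSymmetricMatrix(20, 53)
  curve <- gceOptimalPSW(m)
  expect_length(curve$e, 101L)
  expect_equal(curve$gce, curve$e - curve$pswGrid)
  expect_true(all(diff(curve$e) >= -1e-12))
  expect_true(all(curve$e >= 0 & curve$e <= 1))
})

test_that("the optimal PSW matches a naive exhaustive re-evaluation", {
  m <- randomSymmetricMatrix(15, 54)
  curve <- gceOptimalPSW(m)
  grid <- seq(0, 1, by = 0.01)
  naive <- vapply(grid, function(p) {
    adj <- thresholdAtPSW(m, p)$adjacency
    D <- floydWarshall(adj)
    inv <- 1 / D; diag(inv) <- 0
    mean(rowSums(inv) / (nrow(adj) - 1)) - p
  }, numeric(1))
  expect_equal(curve$gce, naive, tolerance = 1e-12)
  expect_equal(curve$optimalPSW, grid[which.max(naive)])
})

test_that("a star of strongest edges is optimal at small PSW", {
  # hub region correlates 0.9 with everyone; all other pairs 0.05
  n <- 12
  m <- matrix(0.05, n, n)
  m[1, ] <- m[, 1] <- 0.9
  diag(m) <- 1
  curve <- gceOptimalPSW(m)
  # the star (n-1 of n(n-1)/2 edges) already connects everything
  expect_lte(curve$optimalPSW, (n - 1) / (n * (n - 1) / 2) + 0.02)
  expect_gt(curve$optimalPSW, 0)
})

test_that("node metrics take their closed-form values on K3 and stars", {
  k3 <- matrix(1, 3, 3); diag(k3) <- 0
  nm <- nodeMetrics(k3)
  expect_equal(nm$clustering_coefficient, rep(1, 3))
  expect_equal(nm$kcoreness, rep(2L, 3), ignore_attr = TRUE)
  expect_equal(nm$local_efficiency, rep(1, 3))
  expect_equal(nm$strength, rep(2, 3), ignore_attr = TRUE)

  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star <- star + t(star)
  sm <- nodeMetrics(star)
  expect_equal(sm$clustering_coefficient[1], 0)
  expect_equal(sm$strength[1], 4, ignore_attr = TRUE)
  expect_equal(sm$kcoreness, rep(1L, 5), ignore_attr = TRUE)
  expect_equal(sm$local_efficiency[2], 0)
})

test_that("node metrics match igraph on random graphs", {
  skip_if_not_installed("igraph")
  for (seed in 1:30) {
    a <- randomAdjacency(12, 0.3, seed + 100)
    nm <- nodeMetrics(a)
    g <- igraphFrom(a)
    expect_equal(nm$strength, unname(igraph::degree(g)),
                 ignore_attr = TRUE)
    expect_equal(nm$kcoreness, unname(igraph::coreness(g)),
                 ignore_attr = TRUE)
    ccRef <- unname(igraph::transitivity(g, type = "localundirected",
                                         isolates = "zero"))
    expect_equal(nm$clustering_coefficient, ccRef, tolerance = 1e-10)
    leffRef <- vapply(seq_len(12), function(i) {
      nb <- which(a[i, ] > 0)
      if (length(nb) < 2) return(0)
      sub <- igraph::induced_subgraph(g, nb)
      D <- igraph::distances(sub)
      inv <- 1 / D; diag(inv) <- 0
      mean(rowSums(inv) / (length(nb) - 1))
    }, numeric(1))
    expect_equal(nm$local_efficiency, leffRef, tolerance = 1e-10)
  }
})

test_that("within-subject normalization is a proper z-score", {
  m <- randomSymmetricMatrix(10, 55)
  tab <- rbind(
    cbind(subject_id = "S1",
          nodeMetrics(thresholdAtPSW(m, 0.3)$adjacency)),
    cbind(subject_id = "S2",
          nodeMetrics(thresholdAtPSW(m, 0.6)$adjacency)))
  norm <- normalizeWithinSubject(tab)
  for (sid in c("S1", "S2")) {
    z <- norm$strength_z[norm$subject_id == sid]
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
  }
  # scale invariance: doubling raw strengths leaves z-scores unchanged
  tab2 <- tab; tab2$strength <- tab2$strength * 2
  norm2 <- normalizeWithinSubject(tab2)
  expect_equal(norm2$strength_z, norm$strength_z, tolerance = 1e-12)
  # constant metric maps to zeros and is flagged
  tab3 <- tab; tab3$kcoreness <- 3
  norm3 <- normalizeWithinSubject(tab3)
  expect_true(all(norm3$kcoreness_z == 0))
  expect_true(any(grepl("kcoreness", attr(norm3, "degenerate"))))
})

test_that("node-wise GLM recovers planted effects", {
  set.seed(56)
  n <- 200
  ids <- sprintf("S%03d", 1:n)
  grp <- rep(c("I", "II"), each = n / 2)
  meta <- data.frame(subject_id = ids, age = rnorm(n, 73, 8),
                     sex = sample(c("M", "F"), n, replace = TRUE))
  ind <- as.numeric(grp == "II")
  tab <- do.call(rbind, lapply(c("rA", "rB"), function(r)
    data.frame(subject_id = ids, region_label = r,
               m = 2 * ind + 0.1 * meta$age + rnorm(n, sd = 0.01))))
  res <- glmNodeTest(tab, meta, setNames(grp, ids), c("I", "II"),
                     metrics = "m")
  expect_true(all(res$beta > 1.9 & res$beta < 2.1))
  expect_true(all(res$q_value < 0.05))

  # a covariate simulated at zero effect stays within 3 SE of zero
  tab0 <- data.frame(subject_id = ids, region_label = "rC",
                     m = 2 * ind + rnorm(n, sd = 0.5))
  fit <- lm(tab0$m ~ ind + meta$age +
              (as.numeric(factor(meta$sex)) - 1))
  cf <- summary(fit)$coefficients["meta$age", ]
  expect_lt(abs(cf["Estimate"]), 3 * cf["Std. Error"])
})

test_that("rank-deficient designs are rejected explicitly", {
  n <- 20
  ids <- sprintf("S%03d", 1:n)
  grp <- rep(c("I", "II"), each = n / 2)
  meta <- data.frame(subject_id = ids, age = rnorm(n, 73, 8),
                     sex = rep("F", n))
  tab <- data.frame(subject_id = ids, region_label = "rA", m = rnorm(n))
  expect_error(
    glmNodeTest(tab, meta, setNames(grp, ids), c("I", "II"),
                metrics = "m"),
    class = "fcsubtype_rank_deficient")
})

test_that("BH step-up reproduces hand-computed q-values", {
  expect_equal(fdrAdjust(0.04), 0.04)
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand computation with a non-flat pattern:
  # sorted p = (.005, .02, .20), m = 3
  # q3 = .20; q2 = min(.02*3/2, .20) = .03; q1 = min(.005*3, .03) = .015
  expect_equal(fdrAdjust(c(0.20, 0.005, 0.02)), c(0.20, 0.015, 0.03))
  expect_error(fdrAdjust(c(0.5, 0)), class = "fcsubtype_bad_argument")
  expect_error(fdrAdjust(c(0.5, 1.2)), class = "fcsubtype_bad_argument")
})

test_that("proportional thresholding is invariant to uniform rescaling", {
  # a global multiplicative attenuation preserves edge ranks, so the
  # binarized graph — and every binary node metric — is unchanged; only
  # rank-reordering effects are visible to the graph stage
  m <- randomSymmetricMatrix(20, 57)
  scaled <- m * 0.6; diag(scaled) <- 1
  for (p in c(0.1, 0.3, 0.6)) {
    expect_identical(thresholdAtPSW(m, p)$adjacency,
                     thresholdAtPSW(scaled, p)$adjacency)
  }
  expect_identical(gceOptimalPSW(m)$optimalPSW,
                   gceOptimalPSW(scaled)$optimalPSW)
})

test_that("rank-reordering subtype effects are detected node-wise", {
  # subtype II's limbic attenuation + VN/DMN boost reorder edge ranks, so
  # its thresholded graphs differ detectably from CN at limbic nodes
  sim <- suppressMessages(simulateCohort(CohortSpec(seed = 1)))
  fce <- suppressMessages(cohortToFCExperiment(sim))
  meta <- subjectMetadata(fce)
  truth <- setNames(meta$true_group, meta$subject_id)
  tab <- suppressMessages(nodeMetricTable(fce))
  norm <- normalizeWithinSubject(tab)
  rII <- glmNodeTest(norm, meta, truth, c("CN", "II"))
  expect_gt(sum(rII$significant), 0)
  ls <- regionLabels(sim$partition)[
    as.character(networkOf(sim$partition)) == "LS"]
  expect_true(any(rII$region_label[rII$significant] %in% ls))
})
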