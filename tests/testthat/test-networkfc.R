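pairPartition <- function() {
  # two regions per network, all seven networks
  NetworkParcellation(paste0("R", 1:14), rep(networkNames(), each = 2))
}

test_that("a two-region network reduces to |r| of its single pair", {
  part <- pairPartition()
  m <- randomSymmetricMatrix(14, 31)
  v <- intraNetworkFC(m, part)
  for (i in seq_len(7))
    expect_equal(v[[networkNames()[i]]], abs(m[2 * i - 1, 2 * i]))
})

test_that("intra-network FC depends only on |r|", {
  part <- pairPartition()
  m <- randomSymmetricMatrix(14, 32)
  flipped <- -m; diag(flipped) <- 1
  expect_equal(intraNetworkFC(m, part), intraNetworkFC(flipped, part))

  allNeg <- matrix(-1, 14, 14); diag(allNeg) <- 1
  dimnames(allNeg) <- dimnames(m)
  expect_equal(unname(intraNetworkFC(allNeg, part)), rep(1, 7))

  const <- matrix(0.37, 14, 14); diag(const) <- 1
  dimnames(const) <- dimnames(m)
  expect_equal(unname(intraNetworkFC(const, part)), rep(0.37, 7))
})

test_that("intra-network FC equals the naive double-loop mean", {
  part <- NetworkParcellation(paste0("R", 1:10),
                              c(rep("VN", 6), rep("LS", 4)))
  m <- randomSymmetricMatrix(10, 33)
  v <- intraNetworkFC(m, part)
  for (nm in c("VN", "LS")) {
    regs <- which(as.character(networkOf(part)) == nm)
    tot <- 0; cnt <- 0
    for (i in regs) for (j in regs) if (i < j) {
      tot <- tot + abs(m[i, j]); cnt <- cnt + 1
    }
    expect_equal(v[[nm]], tot / cnt, tolerance = 1e-12)
  }
  expect_true(all(v >= 0 & v <= 1))
})

test_that("singleton networks are rejected", {
  part <- NetworkParcellation(paste0("R", 1:3), c("VN", "VN", "LS"))
  expect_error(intraNetworkFC(randomSymmetricMatrix(3, 1), part),
               class = "fcsubtype_bad_argument")
})

test_that("planted contrasts are detected by the statistic", {
  fce <- sharedCohort()
  meta <- subjectMetadata(fce)
  tab <- intraFCTable(fce, groups = setNames(meta$true_group,
                                             meta$subject_id))
  med <- function(g, nw) median(tab$intra_fc[tab$group == g &
                                               tab$network == nw])
  expect_lt(med("II", "LS"), med("CN", "LS"))
  for (nw in networkNames())
    expect_lt(med("I", nw), med("CN", nw))
  expect_equal(nrow(tab), 7L * ncol(fce))
})

test_that("group tests use the conventional test per column", {
  set.seed(41)
  meta <- rbind(simulateMetadata("I", 40), simulateMetadata("II", 30),
                simulateMetadata("CN", 30))
  res <- groupDifferenceTests(meta)
  expect_identical(res$test[res$variable == "age"], "anova")
  expect_identical(res$test[res$variable == "sex"], "chisq")
  expect_identical(res$test[res$variable == "mmse"], "kruskal")
  expect_true(all(res$p_value[!res$degenerate] > 0 &
                    res$p_value[!res$degenerate] <= 1))
  # MMSE separates CN from the subtypes by construction
  expect_lt(res$p_value[res$variable == "mmse"], 1e-6)
})

test_that("a perfectly balanced contingency table gives chi-square 0", {
  meta <- data.frame(group = rep(c("A", "B"), each = 20),
                     sex = rep(c("M", "F"), times = 20))
  res <- groupDifferenceTests(meta, variables = "sex")
  expect_equal(res$statistic, 0)
})

test_that("degenerate columns are flagged, not crashed", {
  meta <- data.frame(group = rep(c("A", "B"), each = 5),
                     mmse = rep(30, 10))
  res <- groupDifferenceTests(meta, variables = "mmse")
  expect_true(res$degenerate)
  expect_true(is.na(res$p_value))
})

test_that("two-group Kruskal-Wallis equals the rank-sum chi-square form", {
  set.seed(43)
  for (rep in 1:5) {
    x <- rnorm(25); y <- rnorm(18, mean = 0.4)
    meta <- data.frame(group = rep(c("A", "B"), c(25, 18)),
                       mmse = c(x, y))
    res <- groupDifferenceTests(meta, variables = "mmse")
    # rank-sum z^2: H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2
    r <- rank(c(x, y)); N <- length(r)
    H <- 12 / (N * (N + 1)) *
      (25 * (mean(r[1:25]) - (N + 1) / 2)^2 +
       18 * (mean(r[26:43]) - (N + 1) / 2)^2)
    expect_equal(res$statistic, H, tolerance = 1e-9)
  }
})

test_that("FC-covariate correlation recovers exact dependence", {
  set.seed(44)
  ids <- sprintf("S%02d", 1:20)
  tab <- data.frame(subject_id = rep(ids, times = 7),
                    group = "I",
                    network = factor(rep(networkNames(), each = 20),
                                     levels = networkNames()),
                    intra_fc = runif(140, 0.2, 0.8))
  meta <- data.frame(subject_id = ids,
                     exact = tab$intra_fc[tab$network == "VN"],
                     flat = rep(1, 20))
  res <- correlateFCWithCovariate(tab, meta, "exact", group = "I")
  expect_equal(res$pearson_r[res$network == "VN"], 1, tolerance = 1e-12)
  expect_error(correlateFCWithCovariate(tab, meta, "flat", group = "I"),
               class = "fcsubtype_zero_variance")
})

test_that("independent covariates yield near-zero correlation", {
  set.seed(45)
  n <- 1000
  ids <- sprintf("S%04d", 1:n)
  tab <- data.frame(subject_id = rep(ids, times = 7), group = "CN",
                    network = factor(rep(networkNames(), each = n),
                                     levels = networkNames()),
                    intra_fc = runif(7 * n))
  meta <- data.frame(subject_id = ids, age = rnorm(n, 70, 8))
  res <- correlateFCWithCovariate(tab, meta, "age", group = "CN")
  expect_true(all(abs(res$pearson_r) < 0.1))
  expect_equal(res$n, rep(n, 7))
})

test_that("missing covariate values are excluded pairwise", {
  ids <- sprintf("S%02d", 1:10)
  tab <- data.frame(subject_id = rep(ids, times = 7), group = "CN",
                    network = factor(rep(networkNames(), each = 10),
                                     levels = networkNames()),
                    intra_fc = runif(70))
  meta <- data.frame(subject_id = ids, mmse = c(NA, NA, rnorm(8, 25)))
  res <- correlateFCWithCovariate(tab, meta, "mmse", group = "CN")
  expect_equal(res$n, rep(8, 7))
})

test_that("t-based Pearson p-value matches cor.test", {
  set.seed(46)
  x <- rnorm(30); y <- 0.4 * x + rnorm(30)
  ct <- cor.test(x, y)
  expect_equal(pearsonPValue(unname(ct$estimate), 30), ct$p.value,
               tolerance = 1e-12)
})
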