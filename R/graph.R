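# Graph-theory stage: proportional thresholding at the global
# cost-efficiency optimum, binary node metrics implemented from first
# principles (BFS shortest paths), within-subject normalization, and
# node-wise covariate-adjusted linear models under BH-FDR.

#' Proportional thresholding by strongest weights
#'
#' Ranks the `n(n-1)/2` upper-triangle entries by `|r|` descending (ties at
#' the cutoff broken by lexicographic (i, j) edge order) and keeps the top
#' `round(psw * n(n-1)/2)` edges, binarized to 1; the diagonal is always 0.
#'
#' @param cm symmetric connectivity matrix.
#' @param psw proportion of strongest weights to retain, in [0, 1].
#' @param positiveOnly rank only positive correlations (default FALSE:
#'   negative edges compete by magnitude).
#' @return List with `adjacency` (binary symmetric, zero diagonal), `psw`,
#'   and `retainedWeights` (original values on kept edges, 0 elsewhere).
#' @export
thresholdAtPSW <- function(cm, psw, positiveOnly = FALSE) {
  assertSquareSymmetric(cm, tol = 1e-8, name = "cm")
  assertScalarNumber(psw, "psw")
  if (psw < 0 || psw > 1)
    fcStop("bad_argument", "psw must lie in [0, 1]")
  n <- nrow(cm)
  v <- vectorizeUpper(cm)                    # row-major (i, j), i < j
  w <- if (positiveOnly) ifelse(v > 0, v, -Inf) else abs(v)
  m <- length(v)
  nKeep <- round(psw * m)
  keep <- integer(0)
  if (nKeep > 0) {
    ord <- order(-w, seq_len(m))             # stable: lexicographic ties
    keep <- ord[seq_len(min(nKeep, m))]
  }
  sel <- logical(m); sel[keep] <- TRUE
  adj <- devectorize(as.numeric(sel), diagonalFill = 0)
  rw <- devectorize(v * sel, diagonalFill = 0)
  dimnames(adj) <- dimnames(rw) <- dimnames(cm)
  list(adjacency = adj, psw = psw, retainedWeights = rw)
}

#' All-pairs shortest path lengths on a binary graph
#'
#' Breadth-first search from every node, implemented by iterated logical
#' neighborhood expansion. Unreachable pairs get Inf.
#'
#' @param adj binary symmetric adjacency matrix, zero diagonal.
#' @return Integer-valued distance matrix (Inf for unreachable pairs).
#' @export
bfsDistances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  if (n == 1L) return(D)
  A <- (adj > 0) * 1
  reach <- diag(n) > 0
  step <- 0L
  repeat {
    step <- step + 1L
    nxt <- ((reach * 1) %*% A) > 0
    new <- nxt & !reach
    if (!any(new)) break
    D[new] <- step
    reach <- reach | new
  }
  dimnames(D) <- dimnames(adj)
  D
}

#' Global efficiency of a binary graph
#'
#' Nodal efficiency `E_i = sum_{j != i} 1/d_ij / (n - 1)` with `d_ij` the
#' unweighted shortest-path length (unreachable pairs contribute 0), and
#' `E` the mean of `E_i`. A complete graph has E = 1, an empty graph E = 0.
#'
#' @param adj binary symmetric adjacency matrix.
#' @return List with `E` (scalar) and `Ei` (per-node efficiencies).
#' @export
globalEfficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2L) return(list(E = 0, Ei = rep(0, n)))
  D <- bfsDistances(adj)
  invD <- 1 / D
  diag(invD) <- 0
  Ei <- rowSums(invD) / (n - 1)
  list(E = mean(Ei), Ei = Ei)
}

#' Global cost-efficiency curve and optimal threshold
#'
#' Evaluates global efficiency at every proportional threshold on the grid
#' 0, 0.01, ..., 1 (101 points), forms `GCE = E - PSW`, and returns the grid
#' argmax (ties go to the smallest PSW, i.e. the cheapest network).
#'
#' @param cm symmetric connectivity matrix.
#' @param pswGrid threshold grid (default `seq(0, 1, by = 0.01)`).
#' @param positiveOnly passed to [thresholdAtPSW()].
#' @return List with `pswGrid`, `e` (efficiencies), `gce` (`e - pswGrid`),
#'   and `optimalPSW`.
#' @export
gceOptimalPSW <- function(cm, pswGrid = seq(0, 1, by = 0.01),
                          positiveOnly = FALSE) {
  e <- vapply(pswGrid, function(p)
    globalEfficiency(thresholdAtPSW(cm, p, positiveOnly)$adjacency)$E,
    numeric(1))
  gce <- e - pswGrid
  best <- which(gce == max(gce))[1]          # smallest psw among ties
  list(pswGrid = pswGrid, e = e, gce = gce,
       optimalPSW = pswGrid[best])
}

coreNumbers <- function(adj) {
  n <- nrow(adj)
  A <- (adj > 0) * 1
  deg <- rowSums(A)
  core <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0L
  while (any(alive)) {
    repeat {
      drop <- alive & deg <= k
      if (!any(drop)) break
      core[drop] <- k
      alive[drop] <- FALSE
      deg <- deg - colSums(A[drop, , drop = FALSE])
      deg[!alive] <- 0
    }
    k <- k + 1L
  }
  core
}

#' Binary node metrics
#'
#' Per-node metrics on a binarized graph, all implemented from first
#' principles: clustering coefficient `2 T_i / (deg_i (deg_i - 1))` (0 for
#' degree < 2); k-coreness (largest k surviving iterative removal of nodes
#' with degree < k); local efficiency (global efficiency of the subgraph
#' induced by the node's neighbors; 0 with fewer than 2 neighbors); and
#' strength (degree on the binary graph).
#'
#' @param adj binary symmetric adjacency matrix with region dimnames.
#' @return data.frame with columns region_label, clustering_coefficient,
#'   kcoreness, local_efficiency, strength.
#' @export
nodeMetrics <- function(adj) {
  n <- nrow(adj)
  A <- (adj > 0) * 1
  deg <- rowSums(A)
  A2 <- A %*% A
  tri <- diag(A2 %*% A) / 2                  # triangles through each node
  cc <- ifelse(deg < 2, 0, 2 * tri / (deg * (deg - 1)))
  leff <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2L) return(0)
    globalEfficiency(A[nb, nb, drop = FALSE])$E
  }, numeric(1))
  labs <- rownames(adj)
  if (is.null(labs)) labs <- paste0("R", seq_len(n))
  data.frame(region_label = labs, clustering_coefficient = cc,
             kcoreness = coreNumbers(A), local_efficiency = leff,
             strength = deg, stringsAsFactors = FALSE, row.names = NULL)
}

#' Node metric table for a cohort
#'
#' For each subject: finds the subject's own GCE-optimal proportional
#' threshold, binarizes, and computes all node metrics. A common fixed
#' threshold can be supplied instead for sensitivity analysis.
#'
#' @param fce an [FCExperiment-class].
#' @param psw NULL (default: per-subject GCE-optimal threshold) or a fixed
#'   proportion applied to every subject.
#' @param positiveOnly passed to [thresholdAtPSW()].
#' @return data.frame with columns subject_id, psw, region_label and the
#'   four metrics.
#' @export
nodeMetricTable <- function(fce, psw = NULL, positiveOnly = FALSE) {
  ids <- colnames(fce)
  rows <- lapply(ids, function(sid) {
    cm <- connectomeOf(fce, sid)
    p <- if (is.null(psw)) gceOptimalPSW(cm,
                                         positiveOnly = positiveOnly)$optimalPSW
         else psw
    g <- thresholdAtPSW(cm, p, positiveOnly)
    cbind(subject_id = sid, psw = p, nodeMetrics(g$adjacency),
          stringsAsFactors = FALSE)
  })
  fcLog("graph", sprintf("node metrics for %d subjects", length(ids)))
  do.call(rbind, rows)
}

#' Within-subject normalization of node metrics
#'
#' Z-scores each metric across a subject's regions (`(x - mean)/sd`),
#' removing between-subject scale and amplitude differences before group
#' comparison. A metric constant across a subject's regions maps to all
#' zeros and is flagged in the `degenerate_*` attribute.
#'
#' @param table output of [nodeMetricTable()].
#' @param metrics metric columns to normalize.
#' @return The table with additional `<metric>_z` columns.
#' @export
normalizeWithinSubject <- function(table,
    metrics = c("clustering_coefficient", "kcoreness",
                "local_efficiency", "strength")) {
  degenerate <- character(0)
  for (m in metrics) {
    zcol <- paste0(m, "_z")
    table[[zcol]] <- NA_real_
    for (sid in unique(table$subject_id)) {
      idx <- table$subject_id == sid
      x <- table[[m]][idx]
      s <- stats::sd(x)
      if (is.na(s) || s == 0) {
        table[[zcol]][idx] <- 0
        degenerate <- c(degenerate, paste(sid, m, sep = ":"))
      } else {
        table[[zcol]][idx] <- (x - mean(x)) / s
      }
    }
  }
  attr(table, "degenerate") <- degenerate
  table
}

#' Node-wise GLM contrast between two groups
#'
#' For every region and metric, fits an ordinary least-squares model
#' `metric ~ group + age + sex` over the subjects in the two contrast
#' groups ("univariate manner": one independent model per node), and
#' reports the group coefficient with its t statistic and two-sided p.
#' Within each metric, p-values are BH-FDR adjusted across regions (the FDR
#' family is one metric x one contrast).
#'
#' @param table normalized node metric table ([normalizeWithinSubject()]).
#' @param meta metadata with subject_id, age, sex.
#' @param groups named vector (by subject id) of group labels.
#' @param contrast character vector of two group labels; the coefficient is
#'   the effect of the second relative to the first.
#' @param metrics metric columns to test (defaults to the z-scored four).
#' @param alpha significance level on q.
#' @return data.frame with columns metric, region_label, beta, t, p_value,
#'   q_value, significant.
#' @export
glmNodeTest <- function(table, meta, groups, contrast,
    metrics = c("clustering_coefficient_z", "kcoreness_z",
                "local_efficiency_z", "strength_z"),
    alpha = 0.05) {
  if (length(contrast) != 2L)
    fcStop("bad_argument", "contrast must name exactly two groups")
  grp <- groups[match(meta$subject_id, names(groups))]
  meta <- meta[!is.na(grp) & grp %in% contrast, , drop = FALSE]
  grp <- grp[!is.na(grp) & grp %in% contrast]
  if (!all(contrast %in% grp))
    fcStop("bad_argument", "both contrast groups must be nonempty")
  gind <- as.numeric(grp == contrast[2])
  sex <- as.numeric(factor(meta$sex, levels = c("F", "M"))) - 1
  X <- cbind(1, gind, age = meta$age, sex = sex)
  if (qr(X)$rank < ncol(X))
    fcStop("rank_deficient",
           "design matrix is rank deficient (e.g. single-sex group)")
  out <- lapply(metrics, function(m) {
    if (!m %in% colnames(table))
      fcStop("bad_argument", "metric column '%s' not found", m)
    regions <- unique(table$region_label)
    wide <- matrix(NA_real_, nrow(meta), length(regions),
                   dimnames = list(meta$subject_id, regions))
    idx <- table$subject_id %in% meta$subject_id
    wide[cbind(table$subject_id[idx], table$region_label[idx])] <-
      table[[m]][idx]
    res <- t(vapply(regions, function(r) {
      fit <- stats::lm(wide[, r] ~ gind + meta$age + sex)
      cf <- summary(fit)$coefficients
      cf["gind", c("Estimate", "t value", "Pr(>|t|)")]
    }, numeric(3)))
    q <- fdrAdjust(pmax(res[, 3], .Machine$double.xmin))
    data.frame(metric = m, region_label = regions, beta = res[, 1],
               t = res[, 2], p_value = res[, 3], q_value = q,
               significant = q < alpha, stringsAsFactors = FALSE,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (`q_(i) = min_{j >= i} p_(j) m / j`, clipped at
#' 1), returned in the input order.
#'
#' @param p p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04))
fdrAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    fcStop("bad_argument", "p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}
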