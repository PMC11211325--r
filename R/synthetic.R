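# Synthetic cohort generator. Emulates a three-group study population: CN
# controls, a "malignant" subtype with globally attenuated functional
# connectivity, and a "benign" subtype attenuated only in the limbic block
# (with a mild compensatory boost of within-VN/DMN connectivity). Group
# templates are block correlation matrices; subjects are finite multivariate
# normal time-series draws from their group template, so realistic sampling
# noise separates subjects within a group.

#' Deterministic region-to-network partition
#'
#' Apportions `nRegions` contiguous regions to the seven networks with the
#' largest-remainder (Hamilton) method, using canonical cortical area
#' proportions (VN .17, SN .17, DAN .11, VAN .12, LS .07, FN .13, DMN .23).
#' With `hemispheres = TRUE` the apportionment is done per hemisphere
#' (labels `L_ROIxxx` / `R_ROIxxx`), which at 360 regions gives 180 per
#' hemisphere.
#'
#' @param nRegions total number of regions (>= 14 so every network gets at
#'   least two regions).
#' @param hemispheres split regions evenly into L/R hemispheres.
#' @return A [NetworkParcellation-class].
#' @export
#' @examples
#' networkSizes(makeParcellation(60))
makeParcellation <- function(nRegions, hemispheres = FALSE) {
  props <- c(VN = 0.17, SN = 0.17, DAN = 0.11, VAN = 0.12,
             LS = 0.07, FN = 0.13, DMN = 0.23)
  apportion <- function(n) {
    if (n < 14L)
      fcStop("bad_argument", "too few regions for all 7 networks")
    q <- props * n
    base <- floor(q)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    # every network needs >= 2 regions; take from the largest blocks
    while (any(base < 2L)) {
      base[which.max(base)] <- base[which.max(base)] - 1L
      base[which.min(base)] <- base[which.min(base)] + 1L
    }
    as.integer(base)
  }
  if (hemispheres) {
    if (nRegions %% 2L != 0L)
      fcStop("bad_argument", "hemispheric parcellation needs an even count")
    per <- nRegions / 2L
    sizes <- apportion(per)
    if (any(sizes < 2L))
      fcStop("bad_argument", "too few regions for all 7 networks")
    network <- rep(rep(networkNames(), times = sizes), 2L)
    hemi <- rep(c("L", "R"), each = per)
    region <- paste0(hemi, "_ROI", sprintf("%03d", c(seq_len(per),
                                                     seq_len(per))))
    NetworkParcellation(region, network, hemisphere = hemi)
  } else {
    sizes <- apportion(nRegions)
    if (any(sizes < 2L))
      fcStop("bad_argument", "too few regions for all 7 networks")
    network <- rep(networkNames(), times = sizes)
    region <- paste0("ROI", sprintf("%03d", seq_len(nRegions)))
    NetworkParcellation(region, network)
  }
}

#' Nearest positive semi-definite correlation repair
#'
#' Clips negative eigenvalues at zero and renormalizes to unit diagonal; the
#' simplest repair that preserves block structure. Symmetry is enforced
#' exactly.
#'
#' @param m symmetric matrix intended as a correlation matrix.
#' @return Symmetric PSD matrix with unit diagonal.
#' @export
nearestPSDCorrelation <- function(m) {
  assertSquareSymmetric(m, tol = 1e-8, name = "m")
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  s <- e$vectors %*% (lam * t(e$vectors))
  d <- diag(s)
  if (any(d <= 0))
    fcStop("not_repairable", "matrix cannot be repaired to a correlation")
  s <- s / sqrt(outer(d, d))
  s <- (s + t(s)) / 2
  diag(s) <- 1
  dimnames(s) <- dimnames(m)
  s
}

#' Block-model template connectivity
#'
#' Builds the CN template: entries within a network block equal
#' `spec@baseWithin`, between-block entries `spec@baseBetween`, unit
#' diagonal, then repaired to the nearest PSD correlation matrix.
#'
#' @param spec a [CohortSpec-class].
#' @param partition a [NetworkParcellation-class] covering `spec@nRegions`
#'   regions.
#' @return Symmetric PSD correlation matrix with region dimnames.
#' @export
makeTemplateFC <- function(spec, partition) {
  n <- spec@nRegions
  if (length(partition) != n)
    fcStop("parcellation_mismatch",
           "partition has %d regions, spec wants %d", length(partition), n)
  net <- as.integer(partition@network)
  same <- outer(net, net, "==")
  m <- ifelse(same, spec@baseWithin, spec@baseBetween)
  diag(m) <- 1
  dimnames(m) <- list(partition@region, partition@region)
  nearestPSDCorrelation(m)
}

#' Apply a subtype effect to a template connectome
#'
#' CN is returned unchanged. Subtype I multiplies every off-diagonal entry
#' by `globalAttenuationI` (global attenuation). Subtype II multiplies
#' entries with at least one endpoint in the limbic network (LS) by
#' `limbicAttenuationII`, then multiplies within-VN and within-DMN entries
#' by `compensationBoostII` and clips to (-1, 1). The result is repaired to
#' the nearest PSD correlation matrix.
#'
#' @param template symmetric template correlation matrix.
#' @param group `"CN"`, `"I"`, or `"II"`.
#' @param spec a [CohortSpec-class].
#' @param partition the matching [NetworkParcellation-class].
#' @return Symmetric PSD correlation matrix.
#' @export
applySubtypeEffect <- function(template, group, spec, partition) {
  net <- partition@network
  m <- template
  off <- !diag(nrow(m)) > 0
  if (group == "CN") {
    # no effect
  } else if (group == "I") {
    m[off] <- m[off] * spec@globalAttenuationI
  } else if (group == "II") {
    inLS <- net == "LS"
    touchLS <- outer(inLS, inLS, "|")
    m[touchLS & off] <- m[touchLS & off] * spec@limbicAttenuationII
    for (nm in c("VN", "DMN")) {
      inN <- net == nm
      blk <- outer(inN, inN, "&") & off
      m[blk] <- pmin(pmax(m[blk] * spec@compensationBoostII,
                          -1 + 1e-12), 1 - 1e-12)
    }
  } else {
    fcStop("unknown_group", "unknown group label '%s'", group)
  }
  diag(m) <- 1
  nearestPSDCorrelation(m)
}

#' Simulate one subject's data from a group template
#'
#' In `"timeseries"` mode, draws `spec@nTimepoints` samples from a zero-mean
#' multivariate normal with covariance equal to the template, so the sample
#' Pearson matrix converges to the template with increasing series length.
#' In `"matrix"` mode, returns the template plus symmetric element-wise
#' Gaussian noise (SD `spec@noiseSd`), re-repaired to a correlation matrix.
#' Uses the current RNG state; seed the stream once per cohort.
#'
#' @param template PSD correlation matrix.
#' @param spec a [CohortSpec-class].
#' @param mode `"timeseries"` or `"matrix"`.
#' @return Regions x timepoints matrix, or a correlation matrix.
#' @export
simulateSubjectData <- function(template, spec,
                                mode = c("timeseries", "matrix")) {
  mode <- match.arg(mode)
  ev <- eigen(template, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    fcStop("not_psd", "template is not positive semi-definite")
  n <- nrow(template)
  if (mode == "timeseries") {
    x <- MASS::mvrnorm(spec@nTimepoints, mu = rep(0, n), Sigma = template,
                       tol = 1e-6)
    ts <- t(x)
    rownames(ts) <- rownames(template)
    ts
  } else {
    if (spec@noiseSd == 0) return(template)
    noise <- matrix(stats::rnorm(n * n, sd = spec@noiseSd), n, n)
    noise <- (noise + t(noise)) / 2
    m <- template + noise
    diag(m) <- 1
    m <- pmin(pmax(m, -1 + 1e-12), 1 - 1e-12)
    diag(m) <- 1
    nearestPSDCorrelation(m)
  }
}

# Group-wise metadata distributions: means (SDs) of the reference clinical
# table, with the observed male fractions. RAVLT_immediate/learning/
# forgetting are verbal-learning scores; MMSE is capped at 30.
metadataDistributions <- function() {
  data.frame(
    group = c("I", "II", "CN"),
    age_mean = c(73.36, 74.22, 70.74), age_sd = c(8.24, 7.16, 6.74),
    male_prob = c(29 / 60, 15 / 22, 21 / 50),
    education_mean = c(15.80, 15.41, 16.94),
    education_sd = c(2.50, 2.56, 2.02),
    mmse_mean = c(22.55, 22.86, 29.14), mmse_sd = c(3.29, 2.85, 0.90),
    ravlt_immediate_mean = c(23.18, 22.23, 49.62),
    ravlt_immediate_sd = c(7.48, 6.29, 8.77),
    ravlt_learning_mean = c(1.77, 1.95, 6.60),
    ravlt_learning_sd = c(1.73, 1.56, 2.43),
    ravlt_forgetting_mean = c(4.75, 4.68, 3.54),
    ravlt_forgetting_sd = c(1.91, 1.81, 3.03),
    stringsAsFactors = FALSE)
}

#' Simulate subject metadata for a group
#'
#' Draws demographic and cognitive scores from group-specific normal
#' distributions whose defaults reproduce the reference cohort's means and
#' SDs (e.g. CN MMSE 29.14 (0.90), subtype I age 73.36 (8.24)). Scores are
#' clipped to valid ranges: age to [40, 110], MMSE to [0, 30], counts to
#' >= 0. Sex is Bernoulli with the group's observed male fraction. Uses the
#' current RNG state.
#'
#' @param group `"CN"`, `"I"`, or `"II"`.
#' @param n number of subjects to draw.
#' @param distributions optional data.frame overriding
#'   the built-in group distributions (same columns).
#' @return data.frame with one row per subject (no subject_id; the cohort
#'   wrapper assigns ids).
#' @export
simulateMetadata <- function(group, n = 1L,
                             distributions = metadataDistributions()) {
  d <- distributions[distributions$group == group, ]
  if (nrow(d) != 1L)
    fcStop("unknown_group", "unknown group label '%s'", group)
  clip <- function(x, lo, hi = Inf) pmin(pmax(x, lo), hi)
  data.frame(
    group = rep(group, n),
    age = clip(stats::rnorm(n, d$age_mean, d$age_sd), 40, 110),
    sex = ifelse(stats::rbinom(n, 1L, d$male_prob) == 1L, "M", "F"),
    education = clip(stats::rnorm(n, d$education_mean, d$education_sd), 0),
    mmse = clip(stats::rnorm(n, d$mmse_mean, d$mmse_sd), 0, 30),
    ravlt_immediate = clip(stats::rnorm(n, d$ravlt_immediate_mean,
                                        d$ravlt_immediate_sd), 0),
    ravlt_learning = clip(stats::rnorm(n, d$ravlt_learning_mean,
                                       d$ravlt_learning_sd), 0),
    ravlt_forgetting = clip(stats::rnorm(n, d$ravlt_forgetting_mean,
                                         d$ravlt_forgetting_sd), 0),
    stringsAsFactors = FALSE)
}

#' Simulate a full cohort
#'
#' Generates the three groups defined by `spec` (subtype I, subtype II, CN):
#' group templates via [makeTemplateFC()] + [applySubtypeEffect()], one data
#' draw per subject via [simulateSubjectData()], and matched metadata via
#' [simulateMetadata()]. Fully deterministic under `spec@seed`.
#'
#' @param spec a [CohortSpec-class].
#' @param partition optional [NetworkParcellation-class]; default
#'   `makeParcellation(spec@nRegions)`.
#' @param mode `"timeseries"` (default) or `"matrix"`.
#' @return A list of class `"FCCohortSim"` with elements `data` (named list
#'   of per-subject matrices), `meta` (data.frame with subject_id, group =
#'   "AD"/"CN" style true labels kept in `true_group`), `templates` (named
#'   list of the three group templates), `partition`, `spec`, `mode`.
#' @export
#' @examples
#' sim <- simulateCohort(CohortSpec(nPerGroup = c(I = 3L, II = 2L, CN = 2L),
#'                                  nRegions = 20, nTimepoints = 50, seed = 7))
#' names(sim$data)
simulateCohort <- function(spec, partition = NULL,
                           mode = c("timeseries", "matrix")) {
  mode <- match.arg(mode)
  if (is.null(partition)) partition <- makeParcellation(spec@nRegions)
  set.seed(spec@seed)
  fcLog("simulate", sprintf(
    "n=%s regions=%d timepoints=%d mode=%s seed=%d",
    paste(spec@nPerGroup, collapse = "/"), spec@nRegions,
    spec@nTimepoints, mode, spec@seed))
  base <- makeTemplateFC(spec, partition)
  groups <- c("I", "II", "CN")
  templates <- lapply(groups, function(g)
    applySubtypeEffect(base, g, spec, partition))
  names(templates) <- groups
  data <- list()
  meta <- NULL
  idx <- 0L
  for (g in groups) {
    ng <- spec@nPerGroup[[g]]
    if (ng == 0L) next
    md <- simulateMetadata(g, ng)
    for (i in seq_len(ng)) {
      idx <- idx + 1L
      sid <- sprintf("S%03d", idx)
      data[[sid]] <- simulateSubjectData(templates[[g]], spec, mode)
    }
    ids <- sprintf("S%03d", (idx - ng + 1L):idx)
    md <- cbind(subject_id = ids, md, stringsAsFactors = FALSE)
    meta <- rbind(meta, md)
  }
  meta$true_group <- meta$group
  meta$group <- ifelse(meta$group == "CN", "CN", "AD")
  rownames(meta) <- meta$subject_id
  structure(list(data = data, meta = meta, templates = templates,
                 partition = partition, spec = spec, mode = mode),
            class = "FCCohortSim")
}

#' Assemble an FCExperiment from a simulated cohort
#'
#' Time-series cohorts are run through [correlationMatrix()]; matrix-mode
#' cohorts are vectorized directly.
#'
#' @param sim result of [simulateCohort()].
#' @return An [FCExperiment-class] with `true_group` in its colData.
#' @export
cohortToFCExperiment <- function(sim) {
  if (sim$mode == "timeseries") {
    buildFCExperiment(sim$data, colData = sim$meta,
                      parcellation = sim$partition)
  } else {
    fc <- vapply(sim$data, vectorizeUpper,
                 numeric(length(sim$partition) *
                         (length(sim$partition) - 1L) / 2L))
    FCExperiment(fc, colData = sim$meta,
                 regionLabels = regionLabels(sim$partition),
                 parcellation = sim$partition)
  }
}
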