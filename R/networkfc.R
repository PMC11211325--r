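# Intra-network functional connectivity and the group-level statistics run
# on it: the per-network mean absolute correlation, omnibus group-difference
# tests, and Pearson associations with demographic / cognitive covariates.

#' Intra-network functional connectivity
#'
#' For each of the seven networks X, the mean of `|r_ij|` over unordered
#' distinct region pairs within X:
#' `2 * sum_{i<j in X} |r_ij| / (n_X (n_X - 1))`. Depends only on `|r|`, so
#' it is invariant to region ordering and sign flips, and always lies in
#' [0, 1]. Networks with fewer than two regions are an error.
#'
#' @param cm symmetric connectivity matrix with region dimnames.
#' @param part a [NetworkParcellation-class] whose regions all appear in
#'   `cm`.
#' @return Named numeric vector, one value per network in canonical order.
#' @export
#' @examples
#' part <- makeParcellation(20)
#' cm <- makeTemplateFC(CohortSpec(nRegions = 20), part)
#' intraNetworkFC(cm, part)
intraNetworkFC <- function(cm, part) {
  assertSquareSymmetric(cm, tol = 1e-8, name = "cm")
  labs <- rownames(cm)
  if (is.null(labs) || !all(part@region %in% labs))
    fcStop("parcellation_mismatch",
           "all partition regions must be present in the matrix")
  present <- networkNames()[networkNames() %in% as.character(part@network)]
  out <- vapply(present, function(nm) {
    regs <- part@region[part@network == nm]
    if (length(regs) < 2L)
      fcStop("bad_argument", "network %s has fewer than 2 regions", nm)
    sub <- cm[regs, regs, drop = FALSE]
    mean(abs(sub[upper.tri(sub)]))
  }, numeric(1))
  out
}

#' Intra-network FC table for a cohort
#'
#' One row per subject and network (seven rows per subject), carrying the
#' subject's group label.
#'
#' @param fce an [FCExperiment-class] with an attached parcellation.
#' @param groups optional named vector (by subject id) of group labels that
#'   override colData's `group` (e.g. recovered subtypes).
#' @return data.frame with columns subject_id, group, network, intra_fc.
#' @export
intraFCTable <- function(fce, groups = NULL) {
  part <- parcellationOf(fce)
  if (is.null(part))
    fcStop("bad_shape", "FCExperiment has no attached parcellation")
  ids <- colnames(fce)
  grp <- colData(fce)$group
  names(grp) <- ids
  if (!is.null(groups)) grp[names(groups)] <- groups
  rows <- lapply(ids, function(sid) {
    v <- intraNetworkFC(connectomeOf(fce, sid), part)
    data.frame(subject_id = sid, group = grp[[sid]],
               network = factor(names(v), levels = networkNames()),
               intra_fc = unname(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Omnibus group-difference tests on a metadata table
#'
#' Applies the conventional test per column type: one-way ANOVA for age,
#' a chi-squared test on the sex contingency table, and Kruskal-Wallis for
#' education and the cognitive scores (and any other numeric column).
#' Columns that are constant within the pooled sample are flagged
#' (`degenerate = TRUE`, statistic NA) rather than crashing.
#'
#' @param meta data.frame with a `group` column plus the variables to test.
#' @param variables columns to test; defaults to every column other than
#'   subject_id / group / true_group.
#' @return data.frame with columns variable, test, statistic, df, p_value,
#'   degenerate.
#' @export
groupDifferenceTests <- function(meta, variables = NULL) {
  if (!"group" %in% colnames(meta))
    fcStop("bad_shape", "metadata needs a 'group' column")
  grp <- factor(meta$group)
  if (nlevels(droplevels(grp)) < 2L)
    fcStop("bad_argument", "need at least 2 nonempty groups")
  if (is.null(variables))
    variables <- setdiff(colnames(meta),
                         c("subject_id", "group", "true_group"))
  testFor <- function(v) {
    if (v == "age") "anova"
    else if (v == "sex" || !is.numeric(meta[[v]])) "chisq"
    else "kruskal"
  }
  rows <- lapply(variables, function(v) {
    x <- meta[[v]]
    kind <- testFor(v)
    degenerate <- length(unique(x[!is.na(x)])) < 2L
    if (degenerate)
      return(data.frame(variable = v, test = kind, statistic = NA_real_,
                        df = NA_real_, p_value = NA_real_,
                        degenerate = TRUE))
    if (kind == "anova") {
      fit <- stats::aov(x ~ grp)
      s <- summary(fit)[[1]]
      data.frame(variable = v, test = "anova", statistic = s$`F value`[1],
                 df = s$Df[1], p_value = s$`Pr(>F)`[1], degenerate = FALSE)
    } else if (kind == "chisq") {
      tab <- table(x, grp)
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(variable = v, test = "chisq",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 degenerate = FALSE)
    } else {
      kt <- stats::kruskal.test(x ~ grp)
      data.frame(variable = v, test = "kruskal",
                 statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p_value = kt$p.value,
                 degenerate = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Pearson association between intra-network FC and a covariate
#'
#' Within one group, correlates each network's intra-network FC with a
#' metadata covariate: Pearson r with the two-sided p-value from the t
#' distribution on n - 2 degrees of freedom. Missing covariate values are
#' excluded pairwise. P-values are reported raw (uncorrected), matching how
#' such network-covariate associations are conventionally reported; the
#' node-wise graph analyses own FDR correction.
#'
#' @param fcTable output of [intraFCTable()].
#' @param meta metadata data.frame with subject_id and the covariate.
#' @param covariate covariate column name (e.g. "age", "mmse").
#' @param group group label to restrict to, or NULL for all subjects.
#' @return data.frame with columns group, network, covariate, pearson_r,
#'   p_value, n.
#' @export
correlateFCWithCovariate <- function(fcTable, meta, covariate,
                                     group = NULL) {
  if (!covariate %in% colnames(meta))
    fcStop("bad_argument", "covariate '%s' not in metadata", covariate)
  tab <- fcTable
  if (!is.null(group)) tab <- tab[tab$group == group, , drop = FALSE]
  cov <- stats::setNames(meta[[covariate]], meta$subject_id)
  rows <- lapply(networkNames(), function(nm) {
    sub <- tab[tab$network == nm, , drop = FALSE]
    x <- sub$intra_fc
    y <- cov[sub$subject_id]
    keep <- stats::complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L)
      fcStop("bad_argument", "fewer than 3 complete pairs for %s", nm)
    if (stats::sd(y) == 0)
      fcStop("zero_variance", "covariate '%s' has zero variance", covariate)
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(group = if (is.null(group)) "all" else group, network = nm,
               covariate = covariate, pearson_r = unname(ct$estimate),
               p_value = ct$p.value, n = length(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-sided p-value for a Pearson correlation
#'
#' The t-based formula: `t = r sqrt(n - 2) / sqrt(1 - r^2)`, p from the t
#' distribution with n - 2 degrees of freedom.
#'
#' @param r Pearson correlation.
#' @param n number of pairs.
#' @return Two-sided p-value.
#' @export
#' @examples
#' pearsonPValue(-0.272, 60)
pearsonPValue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tstat), df = n - 2)
}
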