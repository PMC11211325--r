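#' NetworkParcellation: region-to-network lookup
#'
#' Maps each cortical region label to one of the seven canonical functional
#' networks (see [networkNames()]). Optionally carries a hemisphere code per
#' region. Regions are unique; every region belongs to exactly one network.
#'
#' @slot region character vector of unique region labels.
#' @slot hemisphere character vector ("L"/"R") or NA when hemispheres are not
#'   modelled.
#' @slot network factor with levels `networkNames()`, one value per region.
#'
#' @seealso [loadParcellation()], [makeParcellation()], [networkSizes()]
#' @export
setClass("NetworkParcellation",
  representation(region = "character",
                 hemisphere = "character",
                 network = "factor"))

setValidity("NetworkParcellation", function(object) {
  msgs <- character()
  n <- length(object@region)
  if (anyDuplicated(object@region))
    msgs <- c(msgs, "duplicate region labels")
  if (length(object@network) != n)
    msgs <- c(msgs, "network must have one entry per region")
  if (length(object@hemisphere) != n)
    msgs <- c(msgs, "hemisphere must have one entry per region")
  if (!identical(levels(object@network), networkNames()))
    msgs <- c(msgs, "network levels must equal networkNames()")
  if (anyNA(object@network))
    msgs <- c(msgs, "every region needs a network assignment")
  bad <- object@hemisphere[!is.na(object@hemisphere)]
  if (length(bad) && !all(bad %in% c("L", "R")))
    msgs <- c(msgs, "hemisphere codes must be 'L' or 'R'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a NetworkParcellation
#'
#' @param region character vector of unique region labels.
#' @param network character or factor of network assignments; must draw from
#'   `networkNames()` unless `strict = FALSE`, in which case unknown names are
#'   still rejected (the vocabulary is fixed) but order is free.
#' @param hemisphere optional character vector of "L"/"R" codes.
#' @param strict reject network names outside the seven-name vocabulary.
#' @return A [NetworkParcellation-class] object.
#' @export
#' @examples
#' NetworkParcellation(c("r1", "r2"), c("VN", "LS"))
NetworkParcellation <- function(region, network, hemisphere = NULL,
                                strict = TRUE) {
  region <- as.character(region)
  network <- as.character(network)
  unknown <- setdiff(unique(network), networkNames())
  if (length(unknown) && strict)
    fcStop("unknown_network", "unknown network name(s): %s",
           paste(unknown, collapse = ", "))
  if (anyDuplicated(region))
    fcStop("duplicate_region", "duplicate region label(s): %s",
           paste(unique(region[duplicated(region)]), collapse = ", "))
  if (is.null(hemisphere)) hemisphere <- rep(NA_character_, length(region))
  if (length(unknown)) {
    # permissive mode: coerce unknown names to NA-free extended factor is not
    # allowed by the class; map them onto the canonical levels is wrong too,
    # so permissive mode only relaxes the error into dropping those rows.
    keep <- network %in% networkNames()
    region <- region[keep]; network <- network[keep]
    hemisphere <- hemisphere[keep]
  }
  new("NetworkParcellation", region = region,
      hemisphere = as.character(hemisphere),
      network = factor(network, levels = networkNames()))
}

setMethod("show", "NetworkParcellation", function(object) {
  cat("NetworkParcellation with", length(object@region), "regions\n")
  print(table(object@network))
})

#' @describeIn NetworkParcellation-class number of regions
#' @param x a NetworkParcellation
#' @export
setMethod("length", "NetworkParcellation", function(x) length(x@region))

#' Accessors for NetworkParcellation
#'
#' `regionLabels()` returns region labels, `networkOf()` the network factor
#' (named by region), `networkSizes()` the per-network region counts, and
#' `hemisphereOf()` the hemisphere codes.
#'
#' @param part a [NetworkParcellation-class].
#' @return character vector, named factor, named integer vector, or character
#'   vector respectively.
#' @export
regionLabels <- function(part) part@region

#' @rdname regionLabels
#' @export
networkOf <- function(part) stats::setNames(part@network, part@region)

#' @rdname regionLabels
#' @export
networkSizes <- function(part) {
  tab <- table(part@network)
  stats::setNames(as.integer(tab), names(tab))
}

#' @rdname regionLabels
#' @export
hemisphereOf <- function(part) stats::setNames(part@hemisphere, part@region)

#' CohortSpec: parameters of the synthetic cohort generator
#'
#' Describes a simulated study population with three groups: cognitively
#' normal controls (CN), a "malignant" subtype I with globally attenuated
#' functional connectivity, and a "benign" subtype II whose attenuation is
#' confined to the limbic block, with an optional mild compensatory boost of
#' within-VN and within-DMN connectivity.
#'
#' @slot nPerGroup named integer vector (names "I", "II", "CN").
#' @slot nRegions number of cortical regions.
#' @slot nTimepoints length of each region-averaged series.
#' @slot baseWithin baseline correlation inside a network block, in (0, 1).
#' @slot baseBetween baseline correlation between blocks, in (0, 1); must be
#'   below `baseWithin`.
#' @slot globalAttenuationI multiplier in (0, 1] applied to every off-diagonal
#'   entry for subtype I.
#' @slot limbicAttenuationII multiplier in (0, 1] applied to entries touching
#'   the limbic network for subtype II.
#' @slot compensationBoostII multiplier >= 1 applied to within-VN and
#'   within-DMN entries for subtype II.
#' @slot noiseSd element-wise noise SD used in direct-matrix mode.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortSpec",
  representation(nPerGroup = "integer", nRegions = "integer",
                 nTimepoints = "integer", baseWithin = "numeric",
                 baseBetween = "numeric", globalAttenuationI = "numeric",
                 limbicAttenuationII = "numeric",
                 compensationBoostII = "numeric", noiseSd = "numeric",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  msgs <- character()
  if (!identical(names(object@nPerGroup), c("I", "II", "CN")))
    msgs <- c(msgs, "nPerGroup must be named I, II, CN")
  if (any(object@nPerGroup < 0L)) msgs <- c(msgs, "group sizes must be >= 0")
  if (object@nRegions < 2L) msgs <- c(msgs, "nRegions must be >= 2")
  if (object@nTimepoints < 3L) msgs <- c(msgs, "nTimepoints must be >= 3")
  if (!(object@baseWithin > 0 && object@baseWithin < 1))
    msgs <- c(msgs, "baseWithin must lie in (0, 1)")
  if (!(object@baseBetween > 0 && object@baseBetween < 1))
    msgs <- c(msgs, "baseBetween must lie in (0, 1)")
  if (object@baseWithin <= object@baseBetween)
    msgs <- c(msgs, "baseWithin must exceed baseBetween")
  if (!(object@globalAttenuationI > 0 && object@globalAttenuationI <= 1))
    msgs <- c(msgs, "globalAttenuationI must lie in (0, 1]")
  if (!(object@limbicAttenuationII > 0 && object@limbicAttenuationII <= 1))
    msgs <- c(msgs, "limbicAttenuationII must lie in (0, 1]")
  if (object@compensationBoostII < 1)
    msgs <- c(msgs, "compensationBoostII must be >= 1")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CohortSpec
#'
#' Defaults define the reference simulation: 60 regions partitioned into the
#' seven networks, 200 timepoints, 20/10/15 subjects in subtype I / subtype
#' II / CN, within-network baseline r = 0.5 against 0.15 between networks,
#' subtype I attenuated globally by 0.6, subtype II attenuated by 0.6 in the
#' limbic block with a 1.1 within-VN/DMN boost. The full 360-region scale is
#' reached by setting `nRegions = 360`.
#'
#' @param nPerGroup named vector of group sizes (names "I", "II", "CN").
#' @param nRegions,nTimepoints dimensions of each subject's data.
#' @param baseWithin,baseBetween block-model baseline correlations.
#' @param globalAttenuationI,limbicAttenuationII,compensationBoostII subtype
#'   effect multipliers; see [CohortSpec-class].
#' @param noiseSd element-wise noise SD for direct-matrix simulation.
#' @param seed integer seed controlling all randomness downstream.
#' @return A validated [CohortSpec-class] object.
#' @export
#' @examples
#' CohortSpec(seed = 1)
CohortSpec <- function(nPerGroup = c(I = 20L, II = 10L, CN = 15L),
                       nRegions = 60, nTimepoints = 200,
                       baseWithin = 0.5, baseBetween = 0.15,
                       globalAttenuationI = 0.6,
                       limbicAttenuationII = 0.6,
                       compensationBoostII = 1.1,
                       noiseSd = 0.05, seed = 1L) {
  npg <- as.integer(nPerGroup)
  names(npg) <- names(nPerGroup)
  new("CohortSpec", nPerGroup = npg, nRegions = as.integer(nRegions),
      nTimepoints = as.integer(nTimepoints), baseWithin = baseWithin,
      baseBetween = baseBetween, globalAttenuationI = globalAttenuationI,
      limbicAttenuationII = limbicAttenuationII,
      compensationBoostII = compensationBoostII, noiseSd = noiseSd,
      seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nRegions, "regions x", object@nTimepoints,
      "timepoints; n =", paste(sprintf("%s:%d", names(object@nPerGroup),
                                       object@nPerGroup), collapse = ", "),
      "\n  attenuation I:", object@globalAttenuationI,
      " limbic II:", object@limbicAttenuationII,
      " boost II:", object@compensationBoostII,
      " seed:", object@seed, "\n")
})

#' FCExperiment: a cohort of vectorized connectomes
#'
#' A [SummarizedExperiment-class] whose single assay `"fc"` holds one column
#' per subject and one row per region pair (the strict upper triangle of the
#' connectivity matrix, row-major over pairs i < j). Subject metadata lives
#' in `colData`; the region labels and the [NetworkParcellation-class] live
#' in `metadata()` under `"regionLabels"` and `"parcellation"`.
#'
#' @seealso [FCExperiment()], [fcMatrix()], [connectomeOf()]
#' @export
setClass("FCExperiment", contains = "SummarizedExperiment")

setValidity("FCExperiment", function(object) {
  msgs <- character()
  if (!"fc" %in% assayNames(object))
    msgs <- c(msgs, "assay 'fc' is required")
  labs <- S4Vectors::metadata(object)$regionLabels
  if (is.null(labs)) {
    msgs <- c(msgs, "metadata()$regionLabels is required")
  } else {
    n <- length(labs)
    if (nrow(object) != n * (n - 1L) / 2L)
      msgs <- c(msgs, "assay rows must equal n(n-1)/2 for n regions")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an FCExperiment
#'
#' @param fc numeric matrix of vectorized upper-triangle connectivity, one
#'   column per subject, `n(n-1)/2` rows for `n` regions.
#' @param colData data.frame (or DataFrame) of subject metadata, one row per
#'   column of `fc`; rownames become subject ids if `fc` has no colnames.
#' @param regionLabels character vector of the `n` region labels in matrix
#'   order.
#' @param parcellation optional [NetworkParcellation-class] covering the
#'   regions.
#' @return An [FCExperiment-class].
#' @export
FCExperiment <- function(fc, colData, regionLabels, parcellation = NULL) {
  fc <- as.matrix(fc)
  if (is.null(colnames(fc)) && !is.null(rownames(colData)))
    colnames(fc) <- rownames(colData)
  md <- list(regionLabels = as.character(regionLabels))
  if (!is.null(parcellation)) {
    if (!all(regionLabels %in% regionLabels(parcellation)))
      fcStop("parcellation_mismatch",
             "parcellation does not cover all region labels")
    md$parcellation <- parcellation
  }
  se <- SummarizedExperiment(assays = list(fc = fc),
                             colData = S4Vectors::DataFrame(colData),
                             metadata = md)
  new("FCExperiment", se)
}

setMethod("show", "FCExperiment", function(object) {
  labs <- S4Vectors::metadata(object)$regionLabels
  cat("FCExperiment:", ncol(object), "subjects,", length(labs),
      "regions (", nrow(object), "region pairs )\n")
  if ("group" %in% colnames(colData(object)))
    print(table(colData(object)$group))
})

#' Accessors for FCExperiment
#'
#' `fcMatrix()` returns the edge-by-subject assay; `connectomeOf()` rebuilds
#' one subject's full symmetric connectivity matrix (unit diagonal);
#' `parcellationOf()` returns the attached parcellation.
#'
#' @param x an [FCExperiment-class].
#' @param subject subject id or column index.
#' @return numeric matrix, symmetric matrix, or NetworkParcellation.
#' @export
fcMatrix <- function(x) assay(x, "fc")

#' @rdname fcMatrix
#' @export
connectomeOf <- function(x, subject) {
  v <- assay(x, "fc")[, subject]
  labs <- S4Vectors::metadata(x)$regionLabels
  m <- devectorize(v, diagonalFill = 1)
  dimnames(m) <- list(labs, labs)
  m
}

#' @rdname fcMatrix
#' @export
parcellationOf <- function(x) S4Vectors::metadata(x)$parcellation

#' @rdname fcMatrix
#' @export
subjectMetadata <- function(x) as.data.frame(colData(x))

#' SubtypeClustering: result of autoencoder + Ward subtyping
#'
#' Holds the selected partition of the clustered subjects together with the
#' full model-selection trace (silhouette and Davies-Bouldin at every
#' candidate k), the latent embedding, and the autoencoder's final training
#' loss.
#'
#' @slot subjectIds character vector of clustered subject ids.
#' @slot labels integer cluster labels, relabelled so cluster 1 is largest.
#' @slot k selected number of clusters.
#' @slot quality data.frame with columns k, silhouette, davies_bouldin.
#' @slot embedding numeric matrix, subjects x latent dimensions.
#' @slot finalTrainLoss final mean squared reconstruction error.
#' @export
setClass("SubtypeClustering",
  representation(subjectIds = "character", labels = "integer",
                 k = "integer", quality = "data.frame",
                 embedding = "matrix", finalTrainLoss = "numeric"))

setValidity("SubtypeClustering", function(object) {
  msgs <- character()
  if (length(object@labels) != length(object@subjectIds))
    msgs <- c(msgs, "one label per subject required")
  if (length(object@labels) &&
      length(unique(object@labels)) != object@k)
    msgs <- c(msgs, "labels must take exactly k distinct values")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SubtypeClustering", function(object) {
  cat("SubtypeClustering: k =", object@k, "over",
      length(object@subjectIds), "subjects\n")
  print(table(object@labels))
  cat("final reconstruction MSE:",
      format(object@finalTrainLoss, digits = 4), "\n")
})

#' Accessors for SubtypeClustering
#'
#' @param fit a [SubtypeClustering-class].
#' @return `clusterLabels()`: named integer vector; `qualityCurve()`: the
#'   k-by-index data.frame; `latentEmbedding()`: the subjects x latent matrix.
#' @export
clusterLabels <- function(fit) stats::setNames(fit@labels, fit@subjectIds)

#' @rdname clusterLabels
#' @export
qualityCurve <- function(fit) fit@quality

#' @rdname clusterLabels
#' @export
latentEmbedding <- function(fit) fit@embedding
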