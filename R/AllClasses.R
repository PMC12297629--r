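#' @import methods
NULL

TIL_LABELS <- c("TIL_POS", "TIL_NEG", "NECROTIC_OTHER")

#' PatchGrid: a masked lattice of per-patch TIL labels for one slide
#'
#' A \code{PatchGrid} holds the patch-level output of an upstream TIL
#' classifier for a single whole-slide image: each tissue patch sits at a
#' 0-based (row, col) position on a regular lattice and carries one of three
#' labels (\code{TIL_POS}, \code{TIL_NEG}, \code{NECROTIC_OTHER}).
#' Non-tissue background is encoded by absence: coordinates not present in
#' the patch table are background, so the grid is a sparse mask.
#'
#' @slot slideId character(1), slide identifier.
#' @slot patientId character(1), patient the slide belongs to.
#' @slot nRows,nCols integer(1), lattice dimensions (patches).
#' @slot patches data.frame with columns \code{row}, \code{col} (0-based
#'   integers) and \code{label} (factor with the three TIL levels).
#' @slot patchSizePx integer(1), edge length of a patch in pixels (metadata).
#' @slot magnification character(1), scan magnification (metadata).
#'
#' @seealso [readPatchTable()], [computeTILScore()], [binarizeTILMap()]
#' @export
setClass("PatchGrid",
  representation(
    slideId = "character",
    patientId = "character",
    nRows = "integer",
    nCols = "integer",
    patches = "data.frame",
    patchSizePx = "integer",
    magnification = "character"
  ),
  prototype(patchSizePx = 150L, magnification = "20x")
)

setValidity("PatchGrid", function(object) {
  p <- object@patches
  if (!all(c("row", "col", "label") %in% names(p)))
    return("patches must have columns row, col, label")
  if (nrow(p) < 1L)
    return("empty grids are not allowed: at least one patch required")
  if (!is.factor(p$label) || !identical(levels(p$label), TIL_LABELS))
    return("label must be a factor with levels TIL_POS, TIL_NEG, NECROTIC_OTHER")
  if (anyNA(p$label))
    return("patch labels must not be NA")
  if (any(p$row < 0L) || any(p$col < 0L) ||
      any(p$row >= object@nRows) || any(p$col >= object@nCols))
    return("patch coordinates out of range [0, nRows) x [0, nCols)")
  if (anyDuplicated(p[, c("row", "col")]))
    return("duplicate patch coordinates")
  TRUE
})

#' TILScore: fraction of TIL-positive patches among scoreable tissue
#'
#' The TIL score of a slide is the number of TIL-positive patches divided by
#' the number of non-necrotic tissue patches; necrotic/other patches enter
#' neither numerator nor denominator.
#'
#' @slot value numeric(1) in [0, 1].
#' @slot nPos integer(1), TIL-positive patch count.
#' @slot nTissue integer(1), non-necrotic tissue patch count (denominator).
#' @export
setClass("TILScore",
  representation(value = "numeric", nPos = "integer", nTissue = "integer")
)

setValidity("TILScore", function(object) {
  if (object@nTissue < 1L) return("nTissue must be >= 1")
  if (abs(object@value - object@nPos / object@nTissue) > 1e-12)
    return("value must equal nPos / nTissue")
  TRUE
})

#' SpatialWeights: contiguity weights on a masked patch lattice
#'
#' Binary contiguity weights among the tissue patches of a [PatchGrid],
#' restricted to patches actually present (background never enters).
#' Self-inclusion (w_ii = 1) gives the starred Getis-Ord statistic Gi*.
#'
#' @slot n integer(1), number of tissue patches.
#' @slot neighbors list of integer vectors; element i holds the indices j
#'   (1-based, including i itself when self-inclusive) with w_ij > 0.
#' @slot weights list of numeric vectors parallel to \code{neighbors}.
#' @slot scheme character(1), "queen" (8-neighborhood) or "rook" (4).
#' @slot includeSelf logical(1).
#' @export
setClass("SpatialWeights",
  representation(
    n = "integer",
    neighbors = "list",
    weights = "list",
    scheme = "character",
    includeSelf = "logical"
  )
)

setValidity("SpatialWeights", function(object) {
  if (length(object@neighbors) != object@n || length(object@weights) != object@n)
    return("neighbors and weights must have length n")
  if (object@includeSelf &&
      !all(vapply(seq_len(object@n),
                  function(i) i %in% object@neighbors[[i]], logical(1))))
    return("self-inclusion requires i in neighbors[[i]] for all i")
  TRUE
})

#' HotspotMap: per-patch Gi* z-scores aligned to a PatchGrid
#'
#' @slot slideId character(1), source slide.
#' @slot nRows,nCols integer(1), lattice dimensions of the source grid.
#' @slot coords matrix with columns \code{row}, \code{col} (0-based), one row
#'   per tissue patch, aligned with \code{z}.
#' @slot z numeric, Gi* z-score per tissue patch.
#' @slot hotThreshold numeric(1), z cutoff defining a hot patch (default 1.96).
#' @slot degenerate logical(1), TRUE when the binary field was constant (all
#'   z are then 0 by convention).
#' @seealso [localGiStar()], [hotFraction()], [renderHotspotMap()]
#' @export
setClass("HotspotMap",
  representation(
    slideId = "character",
    nRows = "integer",
    nCols = "integer",
    coords = "matrix",
    z = "numeric",
    hotThreshold = "numeric",
    degenerate = "logical"
  ),
  prototype(hotThreshold = 1.96, degenerate = FALSE)
)

setValidity("HotspotMap", function(object) {
  if (nrow(object@coords) != length(object@z))
    return("coords and z must be aligned")
  if (!all(colnames(object@coords) == c("row", "col")))
    return("coords must have columns row, col")
  if (object@degenerate && any(object@z != 0))
    return("degenerate maps must have all-zero z")
  TRUE
})

#' ConsensusVote: cluster-number selection by three internal indices
#'
#' Records, for each candidate k, the Silhouette score, Davies-Bouldin index
#' and Calinski-Harabasz index of a K-means partition, each metric's winning
#' k, and the majority-vote selection (silhouette breaks three-way ties).
#'
#' @slot candidateKs integer vector of evaluated cluster numbers.
#' @slot silhouette,daviesBouldin,calinskiHarabasz numeric vectors parallel
#'   to \code{candidateKs} (NA where a k was skipped).
#' @slot winners named integer(3): best k per metric.
#' @slot selectedK integer(1), consensus choice.
#' @export
setClass("ConsensusVote",
  representation(
    candidateKs = "integer",
    silhouette = "numeric",
    daviesBouldin = "numeric",
    calinskiHarabasz = "numeric",
    winners = "integer",
    selectedK = "integer"
  )
)

setValidity("ConsensusVote", function(object) {
  if (!(object@selectedK %in% object@candidateKs))
    return("selectedK must be one of candidateKs")
  TRUE
})

#' SpatialFeatureSet: encoder/PCA features and cluster labels per slide
#'
#' @slot slideIds character, slide order for all row-aligned slots.
#' @slot rawFeatures matrix (slides x 16384 at the default encoder), encoder
#'   output.
#' @slot pcaScores matrix (slides x kPca), principal-component coordinates.
#' @slot pcaModel list with \code{center}, \code{rotation} (orthonormal
#'   loadings), \code{varShare} (non-increasing explained-variance shares)
#'   and \code{kPca}.
#' @slot clusterLabels integer per slide (0 length until clustering).
#' @slot stilcLabels character per slide, "sTILC1" (TIL-cold) / "sTILC2"
#'   (TIL-hot); 0 length until naming.
#' @slot vote ConsensusVote or NULL (list wrapper) before selection.
#' @export
setClass("SpatialFeatureSet",
  representation(
    slideIds = "character",
    rawFeatures = "matrix",
    pcaScores = "matrix",
    pcaModel = "list",
    clusterLabels = "integer",
    stilcLabels = "character",
    vote = "ANY"
  ),
  prototype(clusterLabels = integer(0), stilcLabels = character(0), vote = NULL)
)

setValidity("SpatialFeatureSet", function(object) {
  n <- length(object@slideIds)
  if (nrow(object@rawFeatures) != n) return("rawFeatures rows must match slideIds")
  if (nrow(object@pcaScores) != n) return("pcaScores rows must match slideIds")
  if (length(object@clusterLabels) && length(object@clusterLabels) != n)
    return("clusterLabels must match slideIds")
  if (length(object@stilcLabels) &&
      !all(object@stilcLabels %in% c("sTILC1", "sTILC2")))
    return("stilcLabels must be sTILC1 or sTILC2")
  TRUE
})

#' ModelComparisonReport: paired evaluation of the M1 and M2 LNM models
#'
#' One evaluation block per cohort (training / validation / ...), each with
#' both models' AUC and Brier score, the DeLong z and two-sided p for the
#' AUC difference, exact Shapley attributions for the TIL-augmented model,
#' and decision-curve net-benefit tables.
#'
#' @slot cohorts named list; each element a list with entries \code{aucM1},
#'   \code{aucM2}, \code{delongZ}, \code{delongP}, \code{brierM1},
#'   \code{brierM2}, \code{shapley} (attribution matrix + importance),
#'   \code{netBenefit} (data.frame threshold x curves).
#' @slot seeds named integer vector of the seeds used.
#' @slot configHash character(1), hash of the run configuration.
#' @export
setClass("ModelComparisonReport",
  representation(cohorts = "list", seeds = "integer", configHash = "character"),
  prototype(configHash = "")
)
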