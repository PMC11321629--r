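#' @import methods
#' @importFrom Matrix Matrix sparseMatrix rowSums colSums t
NULL

setOldClass("hclust")

#' AssociationTable: one dimension's bipartite disease-feature edge list
#'
#' Container for the unweighted bipartite associations of a single data
#' dimension (e.g. disease-gene or disease-symptom links). Edges are unique
#' (disease_id, feature_id) pairs; identifiers are non-empty strings and the
#' disease and feature namespaces must not overlap.
#'
#' @slot dimensionName single string naming the dimension (e.g. "genes").
#' @slot featureNamespace one of "gene", "pathway", "chemical", "symptom".
#' @slot edges data.frame with character columns `disease_id`, `feature_id`.
#'
#' @seealso [associationTable()], [toIncidence()], [readAssociationTable()]
#' @export
setClass("AssociationTable",
  slots = c(
    dimensionName = "character",
    featureNamespace = "character",
    edges = "data.frame"
  )
)

setValidity("AssociationTable", function(object) {
  msg <- character()
  if (length(object@dimensionName) != 1L || !nzchar(object@dimensionName))
    msg <- c(msg, "'dimensionName' must be a single non-empty string")
  if (length(object@featureNamespace) != 1L ||
      !object@featureNamespace %in% c("gene", "pathway", "chemical", "symptom"))
    msg <- c(msg, "'featureNamespace' must be one of gene/pathway/chemical/symptom")
  e <- object@edges
  if (!all(c("disease_id", "feature_id") %in% names(e))) {
    msg <- c(msg, "edges must have columns 'disease_id' and 'feature_id'")
  } else {
    if (!is.character(e$disease_id) || !is.character(e$feature_id))
      msg <- c(msg, "edge identifier columns must be character")
    else {
      if (anyNA(e$disease_id) || anyNA(e$feature_id) ||
          any(!nzchar(e$disease_id)) || any(!nzchar(e$feature_id)))
        msg <- c(msg, "empty or missing identifiers are not allowed")
      if (anyDuplicated(paste(e$disease_id, e$feature_id, sep = "\r")))
        msg <- c(msg, "duplicate edges are not allowed")
      if (length(intersect(unique(e$disease_id), unique(e$feature_id))))
        msg <- c(msg, "disease and feature identifier namespaces overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' IncidenceMatrix: binary disease x feature membership
#'
#' Sparse binary matrix with diseases as rows and features as columns;
#' cell (d, f) is 1 iff disease d is associated with feature f. Rows and
#' columns are kept in lexicographic (C-locale radix) order so all
#' downstream tie-breaking is deterministic.
#'
#' @slot mat sparse `Matrix::dgCMatrix` with 0/1 entries and dimnames.
#' @slot dimensionName dimension label carried over from the edge list.
#' @slot featureNamespace feature namespace label.
#'
#' @seealso [toIncidence()], [filterLowCoverage()], [intersectDiseases()]
#' @export
setClass("IncidenceMatrix",
  slots = c(
    mat = "dgCMatrix",
    dimensionName = "character",
    featureNamespace = "character"
  )
)

setValidity("IncidenceMatrix", function(object) {
  m <- object@mat
  msg <- character()
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "incidence matrix must carry disease and feature names")
  else {
    if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
      msg <- c(msg, "duplicate disease or feature identifiers")
    if (!identical(rownames(m), sort(rownames(m), method = "radix")))
      msg <- c(msg, "disease rows must be in lexicographic order")
    if (!identical(colnames(m), sort(colnames(m), method = "radix")))
      msg <- c(msg, "feature columns must be in lexicographic order")
  }
  if (length(m@x) && !all(m@x == 1))
    msg <- c(msg, "incidence cells must be binary (0/1)")
  if (length(msg)) msg else TRUE
})

#' DiseaseDistanceMatrix: square symmetric disease-disease distances
#'
#' Distances live in \[0, 1\], the diagonal is exactly zero and the matrix is
#' symmetric (checked to 1e-12). Rows/columns are indexed by disease
#' identifier in lexicographic order.
#'
#' @slot values numeric matrix with identical row/column dimnames.
#' @slot metric optional label of the generating metric or "consensus".
#'
#' @seealso [distanceMatrix()], [metricConsensus()], [dimensionConsensus()]
#' @export
setClass("DiseaseDistanceMatrix",
  slots = c(values = "matrix", metric = "character")
)

setValidity("DiseaseDistanceMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "row and column disease identifiers must match")
  if (nrow(v)) {
    if (max(abs(diag(v))) > 1e-12) msg <- c(msg, "diagonal must be zero")
    if (max(abs(v - base::t(v))) > 1e-12) msg <- c(msg, "matrix must be symmetric")
    if (min(v) < -1e-12 || max(v) > 1 + 1e-12)
      msg <- c(msg, "distances must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' ConsensusMatrix: hierarchically averaged family of distance matrices
#'
#' A [DiseaseDistanceMatrix-class] carrying the provenance of the fusion:
#' which input matrices were merged, the Ipsen-Mikhailov-guided merge
#' schedule (a ward.D2 `hclust` tree over the inputs), and the effective
#' convex weight each input contributes to every consensus entry
#' (2^-depth of the leaf in the schedule; the weights sum to 1).
#'
#' @slot inputLabels labels of the merged matrices, schedule leaf order.
#' @slot schedule `hclust` object over the inputs (ward.D2 on IM distance).
#' @slot leafWeights named numeric, effective weight per input label.
#' @slot gamma Lorentzian half-width used for the IM family distance.
#'
#' @seealso [hierarchicalAverage()], [metricConsensus()], [dimensionConsensus()]
#' @export
setClass("ConsensusMatrix",
  contains = "DiseaseDistanceMatrix",
  slots = c(
    inputLabels = "character",
    schedule = "hclust",
    leafWeights = "numeric",
    gamma = "numeric"
  )
)

setValidity("ConsensusMatrix", function(object) {
  msg <- character()
  w <- object@leafWeights
  if (!setequal(names(w), object@inputLabels))
    msg <- c(msg, "leafWeights must be named by the input labels")
  if (length(w) && abs(sum(w) - 1) > 1e-9)
    msg <- c(msg, "leaf weights must sum to 1")
  if (length(msg)) msg else TRUE
})
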