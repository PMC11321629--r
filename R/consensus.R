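#' Build a merge schedule for a matrix family
#'
#' Agglomerative ward.D2 clustering of the family members based on their
#' pairwise Ipsen-Mikhailov distances. The returned `hclust` object is the
#' merge schedule that [hierarchicalAverage()] follows; ties are broken
#' deterministically by the smallest pair indices (the `hclust` convention).
#'
#' @param famdist symmetric matrix from [matrixFamilyDistance()].
#' @return an object of class `hclust` with the family labels as leaves.
#' @export
buildSchedule <- function(famdist) {
  stopifnot(is.matrix(famdist), nrow(famdist) >= 2L)
  stats::hclust(stats::as.dist(famdist), method = "ward.D2")
}

#' Stepwise hierarchical averaging of a matrix family
#'
#' Follows the branching points of `schedule` bottom-up: at every internal
#' node the two child matrices (leaf matrices or previously merged node
#' matrices) are averaged elementwise with equal weight 1/2. The root matrix
#' is the consensus. Because averaging is unweighted per branch, a leaf at
#' depth d contributes the effective weight `2^-d`; the weights are recorded
#' in the result's provenance and always sum to 1, so every consensus entry
#' is the corresponding convex combination of the input entries.
#'
#' @param matrices named list of [DiseaseDistanceMatrix-class] objects over
#'   the same ordered disease set; names must match `schedule$labels`.
#' @param schedule merge schedule from [buildSchedule()].
#' @param gamma optional half-width recorded as provenance.
#' @return a [ConsensusMatrix-class].
#' @examples
#' ids <- c("a", "b")
#' mk <- function(x) diseaseDistanceMatrix(
#'   matrix(c(0, x, x, 0), 2, dimnames = list(ids, ids)))
#' fam <- list(A = mk(0.2), B = mk(0.4), C = mk(0.8))
#' sched <- stats::hclust(stats::as.dist(matrix(
#'   c(0, 1, 9, 1, 0, 9, 9, 9, 0), 3,
#'   dimnames = list(names(fam), names(fam)))), "ward.D2")
#' cons <- hierarchicalAverage(fam, sched)
#' as.matrix(cons)["a", "b"]  # ((0.2 + 0.4)/2 + 0.8)/2 = 0.55
#' @export
hierarchicalAverage <- function(matrices, schedule, gamma = NA_real_) {
  stopifnot(is.list(matrices), inherits(schedule, "hclust"))
  labels <- schedule$labels
  if (!setequal(names(matrices), labels))
    stop("schedule leaves do not match the matrix labels")
  matrices <- matrices[labels]
  ids <- diseaseIds(matrices[[1L]])
  vals <- lapply(matrices, function(m) {
    v <- as.matrix(m)
    if (!identical(dim(v), dim(as.matrix(matrices[[1L]]))))
      stop("matrix shape mismatch in the family")
    if (!identical(rownames(v), ids))
      stop("inconsistent disease ordering across the matrix family")
    v
  })
  k <- length(vals)
  nodeMat <- vector("list", k - 1L)
  nodeW <- vector("list", k - 1L)
  unitW <- function(i) { w <- numeric(k); w[i] <- 1; w }
  getMat <- function(idx) if (idx < 0) vals[[-idx]] else nodeMat[[idx]]
  getW <- function(idx) if (idx < 0) unitW(-idx) else nodeW[[idx]]
  for (s in seq_len(k - 1L)) {
    l <- schedule$merge[s, 1L]; r <- schedule$merge[s, 2L]
    nodeMat[[s]] <- (getMat(l) + getMat(r)) / 2
    nodeW[[s]] <- (getW(l) + getW(r)) / 2
  }
  w <- nodeW[[k - 1L]]
  names(w) <- labels
  root <- nodeMat[[k - 1L]]
  new("ConsensusMatrix",
      values = (root + base::t(root)) / 2,
      metric = "consensus",
      inputLabels = labels,
      schedule = schedule,
      leafWeights = w,
      gamma = gamma)
}

## shared fusion driver: family IM distance -> schedule -> stepwise average
.fuseFamily <- function(matrices, gamma, interpretation) {
  fam <- matrixFamilyDistance(matrices, gamma = gamma,
                              interpretation = interpretation)
  schedule <- buildSchedule(fam)
  cons <- hierarchicalAverage(matrices, schedule,
                              gamma = attr(fam, "gamma"))
  attr(cons, "familyDistance") <- fam
  cons
}

#' Metric-level consensus for one data dimension
#'
#' Computes the six metric distance matrices for the dimension, compares
#' them by Ipsen-Mikhailov distance, clusters them (ward.D2), and averages
#' them stepwise along the dendrogram into one robust matrix.
#'
#' @param inc an [IncidenceMatrix-class] for the dimension.
#' @param gamma optional IM half-width (calibrated from the disease count
#'   when `NULL`).
#' @param interpretation adjacency interpretation, see
#'   [matrixFamilyDistance()].
#' @return a [ConsensusMatrix-class] over the six metrics.
#' @export
metricConsensus <- function(inc, gamma = NULL,
                            interpretation = c("distance", "similarity")) {
  interpretation <- match.arg(interpretation)
  .fuseFamily(metricMatrices(inc), gamma, interpretation)
}

#' Dimension-level consensus disease map
#'
#' Fuses the per-dimension consensus matrices (all restricted to the common
#' disease set) into the final consensus disease-to-disease distance map,
#' using the same IM-guided stepwise averaging as the metric level. The
#' dimension dendrogram and the effective dimension weights are retained in
#' the provenance.
#'
#' @param dimensionMatrices named list of [DiseaseDistanceMatrix-class]
#'   objects (typically the per-dimension [metricConsensus()] outputs) over
#'   the identical intersected disease set.
#' @inheritParams metricConsensus
#' @return a [ConsensusMatrix-class] over the dimensions.
#' @export
dimensionConsensus <- function(dimensionMatrices, gamma = NULL,
                               interpretation = c("distance", "similarity")) {
  interpretation <- match.arg(interpretation)
  .fuseFamily(dimensionMatrices, gamma, interpretation)
}

#' Export a merge schedule as Newick
#'
#' @param schedule an `hclust` merge schedule.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeScheduleNewick <- function(schedule, path) {
  stopifnot(inherits(schedule, "hclust"))
  ape::write.tree(ape::as.phylo(schedule), file = path)
  invisible(path)
}

#' Export consensus provenance as JSON
#'
#' Records the input labels, the merge table with heights, the effective
#' leaf weights and the IM half-width used, sufficient to audit how the
#' consensus was assembled.
#'
#' @param x a [ConsensusMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeConsensusProvenance <- function(x, path) {
  stopifnot(is(x, "ConsensusMatrix"))
  jsonlite::write_json(
    list(
      inputs = x@inputLabels,
      merges = apply(x@schedule$merge, 1L, identity, simplify = FALSE),
      heights = x@schedule$height,
      leaf_weights = as.list(x@leafWeights),
      gamma = x@gamma
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
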