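#' Ward.D2 hierarchical clustering of diseases
#'
#' Agglomerative clustering of the consensus disease map with the ward.D2
#' criterion (squared distances inside the Lance-Williams update; input
#' distances are not pre-squared). Tie-breaking is the deterministic
#' index-based `hclust` convention.
#'
#' @param dist a [DiseaseDistanceMatrix-class].
#' @return an `hclust` tree whose labels are the disease identifiers.
#' @export
hclustWard2 <- function(dist) {
  stopifnot(is(dist, "DiseaseDistanceMatrix"))
  stats::hclust(stats::as.dist(as.matrix(dist)), method = "ward.D2")
}

#' Cut a disease tree into k clusters
#'
#' Standard dendrogram cut; cluster ids are renumbered 1..k in order of the
#' first member's appearance in the (lexicographic) disease ordering.
#'
#' @param tree an `hclust` tree (e.g. from [hclustWard2()]).
#' @param k number of clusters, `2 <= k <= n`.
#' @return named integer vector of cluster labels per disease.
#' @export
cutK <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("k out of range [1, ", n, "]")
  raw <- stats::cutree(tree, k = k)
  relab <- match(raw, unique(raw))
  names(relab) <- names(raw)
  relab
}

#' Dunn cluster-validity index
#'
#' Minimum between-cluster distance divided by the maximum cluster diameter
#' (largest within-cluster distance). Higher means better separated. When
#' every cluster has zero diameter (all singletons or duplicated points) the
#' index is `+Inf` with a warning.
#'
#' @param dist a [DiseaseDistanceMatrix-class].
#' @param labels integer cluster labels named by (or ordered as) the
#'   diseases; at least 2 clusters.
#' @return a non-negative scalar (possibly `Inf`).
#' @export
dunnIndex <- function(dist, labels) {
  stopifnot(is(dist, "DiseaseDistanceMatrix"))
  v <- as.matrix(dist)
  if (!is.null(names(labels))) labels <- labels[rownames(v)]
  labels <- as.integer(factor(labels))
  if (length(labels) != nrow(v)) stop("labels do not match the matrix")
  if (length(unique(labels)) < 2L) stop("need at least 2 clusters")
  cl <- unique(labels)
  sep <- Inf
  diam <- 0
  for (ci in cl) {
    ii <- labels == ci
    if (sum(ii) > 1L) diam <- max(diam, max(v[ii, ii]))
    oo <- !ii
    if (any(oo)) sep <- min(sep, min(v[ii, oo, drop = FALSE]))
  }
  if (diam == 0) {
    warning("all clusters have zero diameter; Dunn index is +Inf")
    return(Inf)
  }
  sep / diam
}

#' Dunn-index scan over cut sizes
#'
#' Cuts the tree into `k = 2 .. kMax` clusters and computes the Dunn index
#' for each cut. Local maxima are flagged plateau-aware: a maximal run of
#' equal values strictly above both neighboring values (boundary runs are
#' not flagged). The selected number of clusters is the smallest `k` of the
#' first flagged run; it is a reported suggestion and should be overridden
#' when domain knowledge argues for a different cut.
#'
#' @param dist a [DiseaseDistanceMatrix-class].
#' @param tree matching `hclust` tree (computed from `dist` when `NULL`).
#' @param kMax largest cut size (capped at `n - 1`).
#' @return data.frame with columns `k`, `dunn`, `is_local_max`, and
#'   attribute `selected_k` (NA when no interior local maximum exists).
#' @export
dunnScan <- function(dist, tree = NULL, kMax = 250L) {
  stopifnot(is(dist, "DiseaseDistanceMatrix"))
  if (is.null(tree)) tree <- hclustWard2(dist)
  n <- nDiseases(dist)
  kMax <- min(as.integer(kMax), n - 1L)
  if (kMax < 2L) stop("kMax must allow at least k = 2")
  ks <- 2L:kMax
  dunn <- vapply(ks, function(k) dunnIndex(dist, cutK(tree, k)), numeric(1))
  isMax <- logical(length(ks))
  ## plateau-aware interior local maxima
  r <- rle(dunn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (j == 1L || j == length(r$values)) next
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L])
      isMax[starts[j]:ends[j]] <- TRUE
  }
  out <- data.frame(k = ks, dunn = dunn, is_local_max = isMax)
  attr(out, "selected_k") <- if (any(isMax)) ks[which(isMax)[1L]] else NA_integer_
  out
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix and embeds the diseases on the
#' top eigenvectors via `stats::cmdscale`. Negative eigenvalues (distances
#' that are not Euclidean-embeddable) are clipped with a warning. To plot a
#' subset of diseases, slice rows from the full embedding rather than
#' re-embedding the subset, so coordinates stay comparable across clusters.
#'
#' @param dist a [DiseaseDistanceMatrix-class].
#' @param dims embedding dimension (default 2).
#' @return numeric matrix of coordinates, one row per disease.
#' @export
classicalMds <- function(dist, dims = 2L) {
  stopifnot(is(dist, "DiseaseDistanceMatrix"))
  n <- nDiseases(dist)
  if (dims > n - 1L) stop("dims must be at most n - 1")
  v <- as.matrix(dist)
  if (all(v == 0)) {
    coords <- matrix(0, n, dims, dimnames = list(rownames(v), NULL))
    return(coords)
  }
  res <- stats::cmdscale(stats::as.dist(v), k = dims, eig = TRUE)
  if (any(res$eig < -sqrt(.Machine$double.eps) * max(abs(res$eig))))
    warning("negative eigenvalues clipped: distances are not exactly ",
            "Euclidean-embeddable")
  coords <- res$points
  if (ncol(coords) < dims) {   # degenerate: pad collapsed axes with zeros
    coords <- cbind(coords, matrix(0, n, dims - ncol(coords)))
    rownames(coords) <- rownames(v)
  }
  coords
}
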