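#' The six pairwise metrics
#'
#' @return character vector of the supported metric names.
#' @export
metricNames <- function() {
  c("euclidean", "hamming", "cosine", "jaccard", "dice", "overlap")
}

#' Distance between two feature sets under one metric
#'
#' For the similarity-type metrics the returned value is `1 - similarity`:
#' Jaccard `|A∩B|/|A∪B|`, Sorensen-Dice `2|A∩B|/(|A|+|B|)`, overlap
#' `|A∩B|/min(|A|,|B|)` and cosine on binary membership vectors
#' `|A∩B|/sqrt(|A||B|)` (the Ochiai coefficient). Hamming returns the *raw*
#' count of differing positions and Euclidean its square root; for those two
#' the division by the per-matrix maximum happens in [distanceMatrix()].
#'
#' @param metric one of [metricNames()].
#' @param A,B character vectors of feature identifiers.
#' @param universeSize size of the feature universe (must be at least
#'   `|A ∪ B|`); only used for validation, the six metrics depend on the
#'   sets alone.
#' @return a single numeric distance (raw for euclidean/hamming).
#' @examples
#' setDistance("jaccard", c("g1", "g2", "g3"), c("g2", "g3", "g4"), 10)
#' @export
setDistance <- function(metric, A, B, universeSize) {
  metric <- match.arg(metric, metricNames())
  A <- unique(as.character(A)); B <- unique(as.character(B))
  nu <- length(union(A, B))
  if (universeSize < nu)
    stop("universeSize smaller than |A union B|")
  i <- length(intersect(A, B))
  na <- length(A); nb <- length(B)
  if (metric %in% c("cosine", "overlap", "jaccard", "dice") &&
      (na == 0L || nb == 0L) && metric %in% c("cosine", "overlap"))
    stop("undefined similarity: empty feature set for metric '", metric, "'")
  switch(metric,
    jaccard   = if (nu == 0L) 0 else 1 - i / nu,
    dice      = if (na + nb == 0L) 0 else 1 - 2 * i / (na + nb),
    overlap   = 1 - i / min(na, nb),
    cosine    = 1 - i / sqrt(na * nb),
    hamming   = na + nb - 2 * i,
    euclidean = sqrt(na + nb - 2 * i)
  )
}

#' All-pairs disease distance matrix under one metric
#'
#' Computes every pairwise distance on the binary incidence rows. Euclidean
#' and Hamming matrices are normalized to \[0, 1\] by division by their
#' per-matrix maximum (a matrix of identical diseases is left all-zero).
#'
#' @param inc an [IncidenceMatrix-class]; every disease must have at least
#'   one feature (guaranteed after [filterLowCoverage()]).
#' @param metric one of [metricNames()].
#' @return a [DiseaseDistanceMatrix-class].
#' @export
distanceMatrix <- function(inc, metric) {
  stopifnot(is(inc, "IncidenceMatrix"))
  metric <- match.arg(metric, metricNames())
  if (nrow(inc@mat) < 2L) stop("need at least 2 diseases")
  sizes <- Matrix::rowSums(inc@mat)
  if (any(sizes == 0))
    stop("undefined similarity: diseases without features present; ",
         "apply filterLowCoverage() first")
  inter <- as.matrix(Matrix::tcrossprod(inc@mat))
  sa <- matrix(sizes, nrow = length(sizes), ncol = length(sizes))
  sb <- base::t(sa)
  v <- switch(metric,
    jaccard   = 1 - inter / (sa + sb - inter),
    dice      = 1 - 2 * inter / (sa + sb),
    overlap   = 1 - inter / pmin(sa, sb),
    cosine    = 1 - inter / sqrt(sa * sb),
    hamming   = sa + sb - 2 * inter,
    euclidean = sqrt(sa + sb - 2 * inter)
  )
  if (metric %in% c("hamming", "euclidean")) {
    mx <- max(v)
    if (mx > 0) v <- v / mx
  }
  v[v < 0] <- 0          # guard tiny negative round-off
  v[v > 1] <- 1
  dimnames(v) <- list(rownames(inc@mat), rownames(inc@mat))
  diseaseDistanceMatrix(v, metric = metric)
}

#' The full six-metric matrix family for one dimension
#'
#' @param inc an [IncidenceMatrix-class].
#' @return named list of six [DiseaseDistanceMatrix-class] objects, one per
#'   metric in [metricNames()] order.
#' @export
metricMatrices <- function(inc) {
  out <- lapply(metricNames(), function(m) distanceMatrix(inc, m))
  names(out) <- metricNames()
  out
}
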