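## exact hypergeometric tails for 2x2 tables with fixed margins
## a = count in cell (associated, group1); K = row margin (associated total);
## n1 = column margin (group1 size); N = table total.
.hyperGreater <- function(a, K, n1, N) {
  stats::phyper(a - 1, K, N - K, n1, lower.tail = FALSE)
}

.hyperTwoSided <- function(a, K, n1, N) {
  ## sum of point probabilities not exceeding the observed one, with the
  ## usual relative slack against floating-point ties
  lo <- max(0, n1 - (N - K))
  hi <- min(K, n1)
  x <- lo:hi
  p <- stats::dhyper(x, K, N - K, n1)
  pObs <- stats::dhyper(a, K, N - K, n1)
  sum(p[p <= pObs * (1 + 1e-7)])
}

#' Exact p-value for a single 2x2 association table
#'
#' Fisher exact test on the table `rbind(c(a, b), c(c, d))` with rows
#' (associated, not associated) and columns (group 1, group 2).
#' `sided = "greater"` gives the upper hypergeometric tail (association
#' over-represented in group 1); `sided = "two.sided"` sums all table
#' probabilities not exceeding the observed one.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param sided `"greater"` or `"two.sided"`.
#' @return p-value in \[0, 1\].
#' @examples
#' fisherExactP(4, 1, 1, 14)  # 76/15504
#' @export
fisherExactP <- function(a, b, c, d, sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  N <- a + b + c + d
  if (sided == "greater") .hyperGreater(a, a + b, a + c, N)
  else .hyperTwoSided(a, a + b, a + c, N)
}

.sampleOddsRatio <- function(a, b, c, d) {
  if (a == 0 || b == 0 || c == 0 || d == 0) {
    list(or = ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)),
         haldane = TRUE)
  } else {
    list(or = (a * d) / (b * c), haldane = FALSE)
  }
}

.enrichmentRecords <- function(a, b, c, d, featureIds, clusterId, sided) {
  or <- mapply(function(a, b, c, d) .sampleOddsRatio(a, b, c, d),
               a, b, c, d, SIMPLIFY = FALSE)
  N <- a + b + c + d
  p <- if (sided == "greater") {
    .hyperGreater(a, a + b, a + c, N)
  } else {
    mapply(.hyperTwoSided, a, a + b, a + c, N)
  }
  data.frame(
    feature_id = featureIds,
    cluster_id = clusterId,
    a = a, b = b, c = c, d = d,
    odds_ratio = vapply(or, `[[`, numeric(1), "or"),
    haldane = vapply(or, `[[`, logical(1), "haldane"),
    p_nominal = p,
    sided = sided,
    stringsAsFactors = FALSE
  )
}

#' One-versus-all feature enrichment for a disease cluster
#'
#' For every feature of the dimension, tests by an exact hypergeometric
#' (Fisher) test whether the feature is over-represented among the cluster's
#' diseases compared with all remaining diseases. The 2x2 table per feature
#' is (associated / not associated) x (in cluster / not in cluster); the
#' one-sided p-value is the upper (over-representation) tail.
#'
#' @param inc an [IncidenceMatrix-class] restricted to the clustered
#'   diseases.
#' @param labels cluster assignment from [cutK()] (named integer vector).
#' @param clusterId the cluster to test.
#' @param sided `"greater"` (default, over-representation) or `"two.sided"`.
#' @param nClusters,nFeatures multipliers for the Bonferroni adjustment;
#'   default: number of distinct labels and number of features tested in
#'   this dimension.
#' @return data.frame of enrichment records, one row per feature, with the
#'   2x2 counts (`a`,`b`,`c`,`d`), sample odds ratio (Haldane 0.5 correction
#'   flagged in `haldane`), `p_nominal`, `p_adjusted` and `significant`
#'   (`p_adjusted < 0.05`).
#' @export
fisherOneVsAll <- function(inc, labels, clusterId,
                           sided = c("greater", "two.sided"),
                           nClusters = NULL, nFeatures = NULL) {
  sided <- match.arg(sided)
  stopifnot(is(inc, "IncidenceMatrix"))
  ids <- diseaseIds(inc)
  if (is.null(names(labels)) || !all(ids %in% names(labels)))
    stop("labels must be named by the matrix's disease identifiers")
  labels <- labels[ids]
  inCl <- labels == clusterId
  if (!any(inCl)) stop("cluster ", clusterId, " is empty")
  m <- inc@mat
  zero <- Matrix::colSums(m) == 0
  if (any(zero)) {
    warning(sum(zero), " feature(s) absent from all diseases skipped")
    m <- m[, !zero, drop = FALSE]
  }
  a <- Matrix::colSums(m[inCl, , drop = FALSE])
  bAll <- Matrix::colSums(m)
  b <- bAll - a
  cc <- sum(inCl) - a
  dd <- sum(!inCl) - b
  if (is.null(nClusters)) nClusters <- length(unique(labels))
  if (is.null(nFeatures)) nFeatures <- ncol(m)
  rec <- .enrichmentRecords(a, b, cc, dd, colnames(m), clusterId, sided)
  rec$p_adjusted <- bonferroniAdjust(rec$p_nominal, nClusters, nFeatures)
  rec$significant <- rec$p_adjusted < 0.05
  rownames(rec) <- NULL
  rec
}

#' Bonferroni adjustment over clusters and features
#'
#' Multiplies the nominal p-value by the number of clusters and the number
#' of features tested in the dimension (e.g. 71 x 21020 in a gene-dimension
#' analysis with 71 clusters), capped at 1.
#'
#' @param p nominal p-values.
#' @param nClusters number of clusters tested.
#' @param nFeatures number of features tested in the dimension.
#' @return adjusted p-values in \[0, 1\].
#' @export
bonferroniAdjust <- function(p, nClusters, nFeatures) {
  stopifnot(nClusters >= 1, nFeatures >= 1, all(p >= 0))
  pmin(1, p * nClusters * nFeatures)
}

#' Pairwise feature enrichment between two clusters
#'
#' Compares association frequencies between two disease groups directly.
#' The 2x2 table per feature is (associated / not) x (group A / group B);
#' default is the one-sided over-representation-in-A tail, as used for
#' direct pairwise cluster contrasts at a nominal threshold.
#'
#' @param inc an [IncidenceMatrix-class].
#' @param diseasesA,diseasesB disjoint character vectors of disease ids.
#' @param sided `"greater"` (default) or `"two.sided"`.
#' @return data.frame of enrichment records (see [fisherOneVsAll()];
#'   `cluster_id` is `"A_vs_B"`, `p_adjusted` left as the nominal value
#'   multiplied by nothing -- pairwise contrasts are reported nominally, use
#'   [bonferroniAdjust()] to correct if desired).
#' @export
fisherPairwise <- function(inc, diseasesA, diseasesB,
                           sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  stopifnot(is(inc, "IncidenceMatrix"))
  ids <- diseaseIds(inc)
  if (!all(diseasesA %in% ids) || !all(diseasesB %in% ids))
    stop("unknown disease identifiers in the group definitions")
  if (length(intersect(diseasesA, diseasesB)))
    stop("the two groups must be disjoint")
  m <- inc@mat[c(diseasesA, diseasesB), , drop = FALSE]
  m <- m[, Matrix::colSums(m) > 0, drop = FALSE]
  isA <- rownames(m) %in% diseasesA
  a <- Matrix::colSums(m[isA, , drop = FALSE])
  b <- Matrix::colSums(m[!isA, , drop = FALSE])
  cc <- sum(isA) - a
  dd <- sum(!isA) - b
  rec <- .enrichmentRecords(a, b, cc, dd, colnames(m), "A_vs_B", sided)
  rec$p_adjusted <- rec$p_nominal
  rec$significant <- rec$p_nominal < 0.05
  rownames(rec) <- NULL
  rec
}

#' Group-versus-group feature enrichment (two-sided)
#'
#' Convenience wrapper around [fisherPairwise()] with a two-sided test
#' (sum of table probabilities not exceeding the observed one), used e.g.
#' for contrasting a set of cancer clusters against non-cancer clusters.
#'
#' @inheritParams fisherPairwise
#' @return data.frame of enrichment records.
#' @export
fisherGroupVsGroup <- function(inc, diseasesA, diseasesB,
                               sided = c("two.sided", "greater")) {
  fisherPairwise(inc, diseasesA, diseasesB, sided = match.arg(sided))
}

#' Rank features by the number of linked diseases
#'
#' @param table an [AssociationTable-class].
#' @param topN keep the `topN` most frequent features (all when larger than
#'   the feature count).
#' @return data.frame with `feature_id`, `n_diseases_linked`, `rank`,
#'   ordered by descending count with ties ordered by feature identifier.
#' @export
featureFrequency <- function(table, topN = Inf) {
  stopifnot(is(table, "AssociationTable"))
  counts <- base::table(table@edges$feature_id)
  df <- data.frame(
    feature_id = names(counts),
    n_diseases_linked = as.integer(counts),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$n_diseases_linked, df$feature_id, method = "radix"), ,
           drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  utils::head(df, n = min(topN, nrow(df)))
}

#' Spearman rank correlation report
#'
#' Average-rank Spearman correlation with the standard large-sample
#' approximation for the p-value (via `stats::cor.test`). Named vectors are
#' matched on their common names.
#'
#' @param x,y paired numeric vectors (e.g. disease-association degree vs.
#'   publication count per entity); `n >= 3` after pairing.
#' @return list with elements `rho`, `p`, `n`.
#' @export
spearmanReport <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  }
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 paired observations")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
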