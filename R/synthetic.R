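#' Configuration for the synthetic multi-view disease generator
#'
#' Describes the statistical structure the generator plants: `nClusters`
#' disease groups whose members share per-namespace signature feature pools
#' with probability `pIn`, a heavy-tailed background so that a few hub
#' features (TNF- or pain-like) attach to many diseases, per-dimension
#' disease dropout so the six dimensions overlap only partially, and a
#' pathway dimension derived deterministically by grouping gene features.
#'
#' @param nDiseases number of diseases.
#' @param nClusters number of planted clusters (`<= nDiseases`).
#' @param featuresPerNamespace named integer vector of feature-universe
#'   sizes for the five directly generated dimensions (`genes`, `drugs`,
#'   `symptoms`, `chemicals_targeting`, `chemicals_associated`).
#' @param pIn within-cluster signature-feature link probability (scalar or
#'   one value per directly generated dimension).
#' @param pOut background link probability before popularity weighting
#'   (scalar or per-dimension); `0 <= pOut < pIn <= 1`.
#' @param popularityExponent power-law exponent of the feature popularity
#'   weights (weight of the r-th ranked feature is proportional to
#'   `r^-popularityExponent`, normalized to mean 1).
#' @param coverage fraction of diseases present in each dimension, in
#'   (0, 1]; dropout is a uniform random disease subset per dimension.
#' @param genesPerPathway number of gene features grouped into each pathway.
#' @param seed integer seed; per-dimension sub-seeds are derived from it.
#' @return validated list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(nDiseases = 60L,
                            nClusters = 3L,
                            featuresPerNamespace = c(
                              genes = 150L, drugs = 60L, symptoms = 60L,
                              chemicals_targeting = 120L,
                              chemicals_associated = 150L),
                            pIn = 0.9,
                            pOut = 0.05,
                            popularityExponent = 1,
                            coverage = 0.9,
                            genesPerPathway = 5L,
                            seed = 1L) {
  dims <- c("genes", "drugs", "symptoms", "chemicals_targeting",
            "chemicals_associated")
  if (!all(dims %in% names(featuresPerNamespace)))
    stop("featuresPerNamespace must name: ", paste(dims, collapse = ", "))
  pIn <- rep_len(pIn, length(dims)); names(pIn) <- dims
  pOut <- rep_len(pOut, length(dims)); names(pOut) <- dims
  if (any(pOut < 0) || any(pOut >= pIn) || any(pIn > 1))
    stop("need 0 <= pOut < pIn <= 1 in every dimension")
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")
  if (nClusters > nDiseases) stop("nClusters must not exceed nDiseases")
  if (genesPerPathway < 1L) stop("genesPerPathway must be >= 1")
  structure(
    list(nDiseases = as.integer(nDiseases),
         nClusters = as.integer(nClusters),
         featuresPerNamespace = featuresPerNamespace[dims],
         pIn = pIn, pOut = pOut,
         popularityExponent = popularityExponent,
         coverage = coverage,
         genesPerPathway = as.integer(genesPerPathway),
         seed = as.integer(seed)),
    class = "SyntheticConfig"
  )
}

.dimNamespaces <- c(
  genes = "gene", pathways = "pathway", drugs = "chemical",
  symptoms = "symptom", chemicals_targeting = "chemical",
  chemicals_associated = "chemical"
)

.featurePrefix <- c(
  genes = "g", drugs = "dr", symptoms = "sy",
  chemicals_targeting = "ct", chemicals_associated = "ca"
)

## binary membership matrix for one directly generated dimension
.dimMembership <- function(nDis, clusterOf, featIds, pIn, pOut, alpha) {
  nF <- length(featIds)
  K <- max(clusterOf)
  sigPer <- max(1L, floor(nF * 0.6 / K))
  sigPool <- lapply(seq_len(K), function(c)
    seq.int((c - 1L) * sigPer + 1L, c * sigPer))
  ## popularity ranks: random permutation; weight ~ rank^-alpha, mean 1
  rk <- sample.int(nF)
  w <- rk^(-alpha)
  w <- w / mean(w)
  pBg <- pmin(1, pOut * w)
  P <- matrix(rep(pBg, each = nDis), nrow = nDis)
  for (c in seq_len(K))
    P[clusterOf == c, sigPool[[c]]] <- pIn
  M <- matrix(stats::runif(nDis * nF) < P, nrow = nDis)
  ## guarantee every disease carries at least one feature
  empty <- which(rowSums(M) == 0L)
  for (i in empty) M[i, sigPool[[clusterOf[i]]][1L]] <- TRUE
  dimnames(M) <- list(NULL, featIds)
  M
}

#' Generate six synthetic association dimensions with planted clusters
#'
#' Produces one [AssociationTable-class] per dimension (five sampled
#' namespaces plus a pathway dimension derived from the gene dimension by
#' linking a disease to a pathway iff it links at least one of the pathway's
#' member genes) together with the planted ground truth. Deterministic for a
#' fixed config seed; each dimension draws from its own sub-seeded stream so
#' dimensions can be regenerated independently.
#'
#' @param config a [syntheticConfig()].
#' @return list with elements `tables` (named list of six
#'   [AssociationTable-class]) and `truth` (list with `cluster_of`,
#'   `present_in`, `pathway_members`).
#' @examples
#' sim <- generateAssociations(syntheticConfig(nDiseases = 20, seed = 7))
#' names(sim$tables)
#' @export
generateAssociations <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  n <- config$nDiseases
  wd <- max(3L, nchar(as.character(n)))
  dis <- sprintf(paste0("D%0", wd, "d"), seq_len(n))
  clusterOf <- rep_len(seq_len(config$nClusters), n)
  names(clusterOf) <- dis

  dims5 <- names(config$featuresPerNamespace)
  membership <- list()
  for (di in seq_along(dims5)) {
    dn <- dims5[di]
    set.seed((config$seed + 7919L * di) %% 2147483647L)
    nF <- config$featuresPerNamespace[[dn]]
    featIds <- sprintf(paste0(.featurePrefix[[dn]], "%04d"), seq_len(nF))
    membership[[dn]] <- .dimMembership(
      n, clusterOf, featIds,
      config$pIn[[dn]], config$pOut[[dn]], config$popularityExponent)
  }

  ## pathway dimension: deterministic grouping of the gene dimension
  geneIds <- colnames(membership$genes)
  nPath <- ceiling(length(geneIds) / config$genesPerPathway)
  pathwayMembers <- lapply(seq_len(nPath), function(j) {
    idx <- seq.int((j - 1L) * config$genesPerPathway + 1L,
                   min(j * config$genesPerPathway, length(geneIds)))
    geneIds[idx]
  })
  names(pathwayMembers) <- sprintf("pw%04d", seq_len(nPath))
  pathM <- vapply(pathwayMembers, function(g)
    rowSums(membership$genes[, g, drop = FALSE]) > 0L, logical(n))
  colnames(pathM) <- names(pathwayMembers)

  allM <- c(membership["genes"], list(pathways = pathM),
            membership[setdiff(dims5, "genes")])
  allM <- allM[names(.dimNamespaces)]

  ## per-dimension dropout of a uniform random disease subset
  presentIn <- list()
  tables <- list()
  nKeep <- max(config$nClusters, floor(config$coverage * n))
  for (di in seq_along(allM)) {
    dn <- names(allM)[di]
    set.seed((config$seed + 104729L * di) %% 2147483647L)
    keep <- sort(sample.int(n, nKeep))
    presentIn[[dn]] <- dis[keep]
    M <- allM[[dn]][keep, , drop = FALSE]
    rownames(M) <- dis[keep]
    idx <- which(M, arr.ind = TRUE)
    tables[[dn]] <- associationTable(
      data.frame(disease_id = rownames(M)[idx[, 1L]],
                 feature_id = colnames(M)[idx[, 2L]],
                 stringsAsFactors = FALSE),
      dimensionName = dn,
      featureNamespace = .dimNamespaces[[dn]]
    )
  }

  list(
    tables = tables,
    truth = list(
      cluster_of = clusterOf,
      present_in = presentIn,
      pathway_members = pathwayMembers
    )
  )
}

#' Write the generator ground truth as JSON
#'
#' @param truth the `truth` element of [generateAssociations()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(
    list(cluster_of = as.list(truth$cluster_of),
         present_in = truth$present_in,
         pathway_members = truth$pathway_members),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Simulate per-entity publication counts with a target rank correlation
#'
#' Draws heavy-tailed publication counts whose Spearman correlation with the
#' supplied association degrees is approximately `strength`, via a Gaussian
#' copula (latent Pearson correlation `2 sin(pi * strength / 6)`). With
#' `strength = 1` the counts are an exact monotone transform of the degrees
#' (identical tie pattern), so the rank correlation is exactly 1.
#'
#' @param degrees named numeric vector of association degrees per entity
#'   (e.g. the `n_diseases_linked` column of [featureFrequency()]).
#' @param strength target Spearman correlation in \[0, 1\].
#' @param seed integer seed.
#' @return data.frame with `entity_id`, `degree`, `publications`.
#' @export
makePublicationCounts <- function(degrees, strength, seed = 1L) {
  stopifnot(strength >= 0, strength <= 1, length(degrees) >= 3L)
  n <- length(degrees)
  ids <- if (is.null(names(degrees))) as.character(seq_len(n)) else names(degrees)
  set.seed(as.integer(seed))
  if (strength == 1) {
    pubs <- as.integer(round(10 * as.numeric(degrees)))
  } else {
    r <- 2 * sin(pi * strength / 6)
    z <- stats::qnorm((rank(degrees, ties.method = "average") - 0.375) /
                        (n + 0.25))
    y <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
    pubs <- as.integer(floor(exp(5 + 1.5 * y)))
  }
  data.frame(entity_id = ids, degree = as.numeric(degrees),
             publications = pubs, stringsAsFactors = FALSE)
}
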