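#' Top-k nearest diseases by consensus distance
#'
#' Ranks all other diseases by their consensus distance to the query; ties
#' are broken lexicographically by identifier and flagged (a tie at the
#' k-th position means the reported cut is arbitrary within the tied set).
#'
#' @param consensus a [DiseaseDistanceMatrix-class] (typically the
#'   dimension-level [ConsensusMatrix-class]).
#' @param diseaseId query disease identifier.
#' @param k neighborhood size (default 10).
#' @param tags optional named character vector of category tags (e.g.
#'   ICD-10 chapters) to annotate neighbors.
#' @return data.frame with `disease_id`, `distance`, `tied_at_cutoff` and,
#'   when `tags` is given, `tag`.
#' @export
topKNeighbors <- function(consensus, diseaseId, k = 10L, tags = NULL) {
  stopifnot(is(consensus, "DiseaseDistanceMatrix"))
  ids <- diseaseIds(consensus)
  if (!diseaseId %in% ids) stop("unknown disease: ", diseaseId)
  d <- as.matrix(consensus)[diseaseId, ]
  d <- d[names(d) != diseaseId]
  ord <- order(d, names(d), method = "radix")
  k <- min(k, length(d))
  top <- ord[seq_len(k)]
  tied <- k < length(d) && d[ord[k]] == d[ord[k + 1L]]
  out <- data.frame(
    disease_id = names(d)[top],
    distance = unname(d[top]),
    tied_at_cutoff = tied,
    stringsAsFactors = FALSE
  )
  if (!is.null(tags)) out$tag <- unname(tags[out$disease_id])
  out
}

#' Features shared by a disease pair but absent from excluded diseases
#'
#' Returns `features(d1) intersect features(d2)` minus the union of the
#' features of the excluded diseases -- e.g. features shared by T2D and
#' Alzheimer's disease after removing anything also associated with
#' psoriasis, asthma or inflammation.
#'
#' @param inc an [IncidenceMatrix-class].
#' @param pair character vector of exactly two disease identifiers.
#' @param exclude character vector of disease identifiers to subtract
#'   (may be empty).
#' @return sorted character vector of feature identifiers.
#' @export
sharedExclusiveFeatures <- function(inc, pair, exclude = character()) {
  stopifnot(is(inc, "IncidenceMatrix"), length(pair) == 2L)
  ids <- diseaseIds(inc)
  missing <- setdiff(c(pair, exclude), ids)
  if (length(missing))
    stop("unknown disease identifier(s): ", paste(missing, collapse = ", "))
  m <- inc@mat
  featsOf <- function(d) colnames(m)[m[d, ] != 0]
  shared <- intersect(featsOf(pair[1L]), featsOf(pair[2L]))
  if (length(exclude)) {
    excl <- unique(unlist(lapply(exclude, featsOf)))
    shared <- setdiff(shared, excl)
  }
  sort(shared, method = "radix")
}

#' How many further diseases carry a feature
#'
#' Counts the diseases associated with `featureId` over the dimension's
#' full (post-filter, pre-intersection) disease universe; with
#' `excludePair`, the count excludes those diseases ("14 further diseases"
#' style rarity reporting).
#'
#' @param inc an [IncidenceMatrix-class] over the dimension's full disease
#'   universe.
#' @param featureId feature identifier.
#' @param excludePair optional disease identifiers excluded from the count.
#' @return integer count.
#' @export
featureRarity <- function(inc, featureId, excludePair = NULL) {
  stopifnot(is(inc, "IncidenceMatrix"))
  if (!featureId %in% featureIds(inc)) stop("unknown feature: ", featureId)
  carriers <- diseaseIds(inc)[inc@mat[, featureId] != 0]
  length(setdiff(carriers, excludePair))
}

## ---- ICD-10 comparison ----

.icdPattern <- "^[A-Z][0-9]{2}(\\.[0-9A-Za-z]{1,2})?$"

.checkIcd <- function(code) {
  if (length(code) != 1L || is.na(code) || !grepl(.icdPattern, code))
    stop("malformed ICD-10 code: ", code)
  code
}

#' Hierarchical similarity of two ICD-10 codes
#'
#' Level-based similarity over the coding hierarchy: the three levels
#' compared are the chapter letter, the 3-character category and the
#' 4-character subcategory; similarity is the deepest shared level divided
#' by 3. Identical codes score 1, codes sharing only the letter score 1/3,
#' codes differing already in the letter score 0. This level rule is a
#' documented stand-in kept behind this single function so an alternative
#' published weighting can be dropped in.
#'
#' @param codeA,codeB ICD-10 codes such as `"E11.3"`.
#' @return similarity in \[0, 1\].
#' @examples
#' icd10Similarity("E11.3", "E11.5")  # 2/3
#' @export
icd10Similarity <- function(codeA, codeB) {
  a <- .checkIcd(codeA); b <- .checkIcd(codeB)
  if (a == b) return(1)
  if (substr(a, 1L, 1L) != substr(b, 1L, 1L)) return(0)
  if (substr(a, 1L, 3L) != substr(b, 1L, 3L)) return(1 / 3)
  ## same 3-character category, different (or partly absent) subcategory
  2 / 3
}

#' ICD-10-derived disease distance matrix
#'
#' Converts pairwise code similarity to distance (`1 - s`) over the mapped
#' diseases.
#'
#' @param mapping named character vector: disease_id -> ICD-10 code.
#' @param diseases optional disease ids to restrict/order the matrix to.
#' @return a [DiseaseDistanceMatrix-class] over the mapped diseases.
#' @export
icdDistanceMatrix <- function(mapping, diseases = NULL) {
  stopifnot(!is.null(names(mapping)))
  if (!is.null(diseases)) mapping <- mapping[names(mapping) %in% diseases]
  ids <- sort(names(mapping), method = "radix")
  if (length(ids) < 2L) stop("need at least 2 mapped diseases")
  vapply(mapping[ids], .checkIcd, "")
  n <- length(ids)
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- icd10Similarity(mapping[[ids[i]]], mapping[[ids[j]]])
      v[i, j] <- v[j, i] <- 1 - s
    }
  }
  diseaseDistanceMatrix(v, metric = "icd10")
}

#' Compare data dimensions with the ICD-10 coding system
#'
#' Restricts every dimension (and consensus) matrix to the diseases covered
#' by the ICD mapping, builds the ICD distance matrix over the same set, and
#' returns the Ipsen-Mikhailov family distance including the ICD matrix, so
#' the coding hierarchy can be placed on the same dendrogram as the data
#' dimensions.
#'
#' @param matrices named list of [DiseaseDistanceMatrix-class] objects over
#'   a common disease set (per-dimension consensus matrices, optionally the
#'   global consensus).
#' @param mapping named character vector disease_id -> ICD-10 code, covering
#'   at least 3 of the common diseases.
#' @param gamma,interpretation see [matrixFamilyDistance()].
#' @return the IM family-distance matrix with an `"icd10"` row/column;
#'   attribute `diseases` lists the mapped diseases used.
#' @export
icdCompare <- function(matrices, mapping, gamma = NULL,
                       interpretation = c("distance", "similarity")) {
  interpretation <- match.arg(interpretation)
  stopifnot(is.list(matrices), length(matrices) >= 1L)
  ids <- diseaseIds(matrices[[1L]])
  mapped <- sort(intersect(ids, names(mapping)), method = "radix")
  if (length(mapped) < 3L)
    stop("ICD mapping covers fewer than 3 diseases of the matrix family")
  restricted <- lapply(matrices, function(m)
    diseaseDistanceMatrix(as.matrix(m)[mapped, mapped], metric = m@metric))
  restricted$icd10 <- icdDistanceMatrix(mapping, mapped)
  fam <- matrixFamilyDistance(restricted, gamma = gamma,
                              interpretation = interpretation)
  attr(fam, "diseases") <- mapped
  fam
}

#' Read a disease to ICD-10 mapping from TSV
#'
#' Two or three tab-separated columns: disease_id, icd10_code, optional
#' match-quality flag (`exact`/`group`); `#` comments allowed.
#'
#' @param path TSV file path.
#' @return named character vector disease_id -> code, with a `quality`
#'   attribute when the third column is present.
#' @export
readIcdMapping <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", header = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("ICD mapping needs at least 2 columns")
  ## tolerate a header line
  if (grepl("disease", df[1L, 1L], ignore.case = TRUE))
    df <- df[-1L, , drop = FALSE]
  map <- as.character(df[[2L]])
  names(map) <- as.character(df[[1L]])
  vapply(map, .checkIcd, "")
  if (ncol(df) >= 3L) attr(map, "quality") <- as.character(df[[3L]])
  map
}
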