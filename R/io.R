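#' Construct an AssociationTable from an edge data frame
#'
#' Duplicate edges are collapsed silently; a `weight` (third) column, if
#' present, is ignored with a warning since associations are unweighted.
#'
#' @param edges data.frame whose first two columns are disease and feature
#'   identifiers (coerced to character).
#' @param dimensionName label for the data dimension.
#' @param featureNamespace one of `"gene"`, `"pathway"`, `"chemical"`,
#'   `"symptom"`.
#' @return an [AssociationTable-class] object.
#' @examples
#' tab <- associationTable(
#'   data.frame(disease_id = c("d1", "d1", "d2"),
#'              feature_id = c("g1", "g2", "g2")),
#'   "genes", "gene")
#' nDiseases(tab)
#' @export
associationTable <- function(edges, dimensionName, featureNamespace) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  if (ncol(edges) > 2L)
    warning("extra columns in edge list ignored (associations are unweighted)")
  e <- data.frame(
    disease_id = as.character(edges[[1L]]),
    feature_id = as.character(edges[[2L]]),
    stringsAsFactors = FALSE
  )
  e <- unique(e)
  e <- e[order(e$disease_id, e$feature_id, method = "radix"), , drop = FALSE]
  rownames(e) <- NULL
  new("AssociationTable",
      dimensionName = dimensionName,
      featureNamespace = featureNamespace,
      edges = e)
}

#' Read a disease-feature edge list from TSV
#'
#' Expects two tab-separated columns (disease_id, feature_id), UTF-8, with
#' optional `#` comment lines and an optional header line (detected when the
#' first line's fields are `disease_id`/`feature_id`). Duplicate edges are
#' collapsed; the collapsed edge count is reported via `message()`.
#'
#' @param path TSV file path.
#' @inheritParams associationTable
#' @return an [AssociationTable-class].
#' @export
readAssociationTable <- function(path, dimensionName,
                                 featureNamespace = "gene") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty association file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(tolower(trimws(fields[[1L]][1:2])),
                c("disease_id", "feature_id"))) {
    fields <- fields[-1L]
    lineno <- lineno[-1L]
    if (!length(fields)) stop("empty association file: ", path)
  }
  nf <- lengths(fields)
  if (any(nf < 2L))
    stop("malformed row (fewer than 2 tab-separated fields) at line ",
         lineno[which(nf < 2L)[1L]], " of ", path)
  if (any(nf > 2L))
    warning("extra columns in edge list ignored (associations are unweighted)")
  d <- trimws(vapply(fields, `[[`, "", 1L))
  f <- trimws(vapply(fields, `[[`, "", 2L))
  bad <- !nzchar(d) | !nzchar(f)
  if (any(bad))
    stop("blank identifier at line ", lineno[which(bad)[1L]], " of ", path)
  e <- unique(data.frame(disease_id = d, feature_id = f,
                         stringsAsFactors = FALSE))
  message(sprintf("read %d unique edges (%d raw rows) from %s",
                  nrow(e), length(d), path))
  associationTable(e, dimensionName, featureNamespace)
}

#' Write an AssociationTable as a two-column TSV
#'
#' @param x an [AssociationTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAssociationTable <- function(x, path) {
  stopifnot(is(x, "AssociationTable"))
  utils::write.table(x@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert an edge list to a binary incidence matrix
#'
#' Rows (diseases) and columns (features) are placed in lexicographic order,
#' so the result is invariant to the input edge order.
#'
#' @param table an [AssociationTable-class].
#' @return an [IncidenceMatrix-class].
#' @export
toIncidence <- function(table) {
  stopifnot(is(table, "AssociationTable"), nrow(table@edges) > 0L)
  d <- diseaseIds(table)
  f <- featureIds(table)
  m <- Matrix::sparseMatrix(
    i = match(table@edges$disease_id, d),
    j = match(table@edges$feature_id, f),
    x = 1,
    dims = c(length(d), length(f)),
    dimnames = list(d, f)
  )
  new("IncidenceMatrix", mat = m,
      dimensionName = table@dimensionName,
      featureNamespace = table@featureNamespace)
}

#' Per-disease feature-count summary for one dimension
#'
#' Mirrors the usual per-dimension coverage table: first quartile, median,
#' mean and third quartile of the number of features per disease (quantiles
#' use the type-7 definition).
#'
#' @param inc an [IncidenceMatrix-class].
#' @return one-row data.frame with columns `dimension`, `q1`, `median`,
#'   `mean`, `q3`, `n_diseases`.
#' @export
coverageSummary <- function(inc) {
  stopifnot(is(inc, "IncidenceMatrix"))
  counts <- Matrix::rowSums(inc@mat)
  q <- stats::quantile(counts, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(
    dimension = inc@dimensionName,
    q1 = q[1L], median = q[2L], mean = mean(counts), q3 = q[3L],
    n_diseases = length(counts),
    stringsAsFactors = FALSE
  )
}

#' Drop diseases in the lower quartile of feature coverage
#'
#' Removes diseases whose feature count is strictly below the first quartile
#' (type-7 quantile) of the per-disease feature-count distribution; ties at
#' the quartile are retained. Features left without any disease are pruned.
#' The summary is computed on the pre-filter counts.
#'
#' @param inc an [IncidenceMatrix-class] with at least 4 diseases.
#' @return list with elements `incidence` (filtered [IncidenceMatrix-class])
#'   and `summary` (the pre-filter [coverageSummary()] row).
#' @export
filterLowCoverage <- function(inc) {
  stopifnot(is(inc, "IncidenceMatrix"))
  if (nrow(inc@mat) < 4L)
    stop("need at least 4 diseases to apply the quartile filter")
  summ <- coverageSummary(inc)
  counts <- Matrix::rowSums(inc@mat)
  keep <- counts >= summ$q1
  if (!any(keep))
    stop("dimension '", inc@dimensionName, "' empty after filtering")
  m <- inc@mat[keep, , drop = FALSE]
  m <- m[, Matrix::colSums(m) > 0, drop = FALSE]
  list(
    incidence = new("IncidenceMatrix", mat = m,
                    dimensionName = inc@dimensionName,
                    featureNamespace = inc@featureNamespace),
    summary = summ
  )
}

#' Restrict a family of incidence matrices to their common disease set
#'
#' All returned matrices share the identical lexicographically ordered
#' disease vector; features losing all their diseases are dropped.
#'
#' @param incs list of [IncidenceMatrix-class] objects (>= 2).
#' @return list of restricted [IncidenceMatrix-class] objects, same names.
#' @export
intersectDiseases <- function(incs) {
  stopifnot(is.list(incs), length(incs) >= 2L)
  common <- Reduce(intersect, lapply(incs, diseaseIds))
  if (!length(common)) stop("empty disease intersection across dimensions")
  common <- sort(common, method = "radix")
  lapply(incs, function(inc) {
    m <- inc@mat[common, , drop = FALSE]
    m <- m[, Matrix::colSums(m) > 0, drop = FALSE]
    new("IncidenceMatrix", mat = m,
        dimensionName = inc@dimensionName,
        featureNamespace = inc@featureNamespace)
  })
}

#' Drop diseases that have no display name attached
#'
#' Diseases whose identifier is absent from `nameMap` are removed from every
#' matrix consistently. With `strict = FALSE` (default) an empty map is a
#' documented pass-through.
#'
#' @param incs list of [IncidenceMatrix-class] objects.
#' @param nameMap named character vector mapping disease_id to display name.
#' @param strict if `TRUE`, an empty `nameMap` removes everything (and hence
#'   errors); if `FALSE`, an empty map performs no removal.
#' @return list of filtered [IncidenceMatrix-class] objects.
#' @export
excludeUnnamed <- function(incs, nameMap, strict = FALSE) {
  stopifnot(is.list(incs))
  if (!length(nameMap) && !strict) return(incs)
  named <- names(nameMap)[nzchar(nameMap)]
  lapply(incs, function(inc) {
    keep <- diseaseIds(inc) %in% named
    if (!any(keep)) stop("no named disease left in '", inc@dimensionName, "'")
    m <- inc@mat[keep, , drop = FALSE]
    m <- m[, Matrix::colSums(m) > 0, drop = FALSE]
    new("IncidenceMatrix", mat = m,
        dimensionName = inc@dimensionName,
        featureNamespace = inc@featureNamespace)
  })
}

## ---- distance-matrix construction and TSV round trip ----

#' Construct a DiseaseDistanceMatrix from a plain matrix
#'
#' Symmetrizes tiny asymmetries (< 1e-12), forces an exact zero diagonal and
#' validates the \[0, 1\] range.
#'
#' @param values square numeric matrix with disease dimnames.
#' @param metric label recorded on the object.
#' @return a [DiseaseDistanceMatrix-class].
#' @export
diseaseDistanceMatrix <- function(values, metric = NA_character_) {
  stopifnot(is.matrix(values))
  values <- (values + base::t(values)) / 2
  diag(values) <- 0
  new("DiseaseDistanceMatrix", values = values, metric = as.character(metric))
}

#' Read / write square distance matrices as TSV
#'
#' The format has a header row and a leading column of disease identifiers,
#' tab-separated.
#'
#' @param x a [DiseaseDistanceMatrix-class] (for writing).
#' @param path file path.
#' @param metric label to attach on read.
#' @return `readDistanceMatrix` returns a [DiseaseDistanceMatrix-class];
#'   `writeDistanceMatrix` returns `path` invisibly.
#' @export
writeDistanceMatrix <- function(x, path) {
  stopifnot(is(x, "DiseaseDistanceMatrix"))
  df <- data.frame(disease_id = rownames(x@values), x@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path, metric = NA_character_) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  ids <- as.character(df[[1L]])
  v <- as.matrix(df[, -1L, drop = FALSE])
  rownames(v) <- ids
  if (!identical(colnames(v), ids))
    stop("row and column disease identifiers disagree in ", path)
  diseaseDistanceMatrix(v, metric = metric)
}
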