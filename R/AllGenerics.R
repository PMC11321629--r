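#' Accessors for diseaseMapper containers
#'
#' `diseaseIds()` returns the ordered disease identifiers of an object;
#' `featureIds()` the ordered feature identifiers; `dimensionName()` and
#' `featureNamespace()` the dimension metadata; `nDiseases()`/`nFeatures()`
#' the corresponding counts. `leafWeights()` and `mergeSchedule()` expose a
#' consensus matrix's provenance.
#'
#' @param x a package object.
#' @return character vectors, counts, or provenance components.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setGeneric("dimensionName", function(x) standardGeneric("dimensionName"))

#' @rdname accessors
#' @export
setGeneric("featureNamespace", function(x) standardGeneric("featureNamespace"))

#' @rdname accessors
#' @export
setGeneric("nDiseases", function(x) standardGeneric("nDiseases"))

#' @rdname accessors
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname accessors
#' @export
setGeneric("associationEdges", function(x) standardGeneric("associationEdges"))

#' @rdname accessors
#' @export
setGeneric("leafWeights", function(x) standardGeneric("leafWeights"))

#' @rdname accessors
#' @export
setGeneric("mergeSchedule", function(x) standardGeneric("mergeSchedule"))

## ---- AssociationTable ----

#' @rdname accessors
setMethod("diseaseIds", "AssociationTable", function(x)
  sort(unique(x@edges$disease_id), method = "radix"))

#' @rdname accessors
setMethod("featureIds", "AssociationTable", function(x)
  sort(unique(x@edges$feature_id), method = "radix"))

#' @rdname accessors
setMethod("dimensionName", "AssociationTable", function(x) x@dimensionName)

#' @rdname accessors
setMethod("featureNamespace", "AssociationTable", function(x) x@featureNamespace)

#' @rdname accessors
setMethod("nDiseases", "AssociationTable", function(x) length(diseaseIds(x)))

#' @rdname accessors
setMethod("nFeatures", "AssociationTable", function(x) length(featureIds(x)))

#' @rdname accessors
setMethod("associationEdges", "AssociationTable", function(x) x@edges)

setMethod("show", "AssociationTable", function(object) {
  cat(sprintf(
    "AssociationTable '%s' (%s namespace): %d edges, %d diseases, %d features\n",
    object@dimensionName, object@featureNamespace,
    nrow(object@edges), nDiseases(object), nFeatures(object)
  ))
})

## ---- IncidenceMatrix ----

#' @rdname accessors
setMethod("diseaseIds", "IncidenceMatrix", function(x) rownames(x@mat))

#' @rdname accessors
setMethod("featureIds", "IncidenceMatrix", function(x) colnames(x@mat))

#' @rdname accessors
setMethod("dimensionName", "IncidenceMatrix", function(x) x@dimensionName)

#' @rdname accessors
setMethod("featureNamespace", "IncidenceMatrix", function(x) x@featureNamespace)

#' @rdname accessors
setMethod("nDiseases", "IncidenceMatrix", function(x) nrow(x@mat))

#' @rdname accessors
setMethod("nFeatures", "IncidenceMatrix", function(x) ncol(x@mat))

#' @export
#' @method as.matrix IncidenceMatrix
as.matrix.IncidenceMatrix <- function(x, ...) as.matrix(x@mat)

setMethod("show", "IncidenceMatrix", function(object) {
  cat(sprintf(
    "IncidenceMatrix '%s': %d diseases x %d features (%d links)\n",
    object@dimensionName, nrow(object@mat), ncol(object@mat),
    as.integer(sum(object@mat))
  ))
})

## ---- DiseaseDistanceMatrix ----

#' @rdname accessors
setMethod("diseaseIds", "DiseaseDistanceMatrix", function(x) rownames(x@values))

#' @rdname accessors
setMethod("nDiseases", "DiseaseDistanceMatrix", function(x) nrow(x@values))

#' @export
#' @method as.matrix DiseaseDistanceMatrix
as.matrix.DiseaseDistanceMatrix <- function(x, ...) x@values

setMethod("show", "DiseaseDistanceMatrix", function(object) {
  cat(sprintf(
    "DiseaseDistanceMatrix (%s): %d diseases, range [%.3g, %.3g]\n",
    if (length(object@metric)) object@metric else "unlabelled",
    nrow(object@values),
    if (nrow(object@values)) min(object@values) else NA,
    if (nrow(object@values)) max(object@values) else NA
  ))
})

## ---- ConsensusMatrix ----

#' @rdname accessors
setMethod("leafWeights", "ConsensusMatrix", function(x) x@leafWeights)

#' @rdname accessors
setMethod("mergeSchedule", "ConsensusMatrix", function(x) x@schedule)

setMethod("show", "ConsensusMatrix", function(object) {
  cat(sprintf(
    "ConsensusMatrix over {%s}: %d diseases\n  effective weights: %s\n",
    paste(object@inputLabels, collapse = ", "), nrow(object@values),
    paste(sprintf("%s=%.4g", names(object@leafWeights), object@leafWeights),
          collapse = ", ")
  ))
})
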