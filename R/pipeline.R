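#' Read a pipeline configuration from YAML
#'
#' Required keys: `dimensions` (named map dimension -> edge-list TSV path)
#' and `output_dir`. Optional keys with defaults: `namespaces` (named map
#' dimension -> feature namespace; defaults to `"chemical"` for unknown
#' names), `quartile_filter` (TRUE), `interpretation` ("distance"), `k_max`
#' (250), `selected_k` (NULL = Dunn-scan choice), `min_cluster_size` (5),
#' `top_k` (10), `query_diseases` (none), `name_map` (TSV path),
#' `icd_mapping` (TSV path), `seed` (1).
#'
#' @param path YAML file path.
#' @return validated config list of class `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  pipelineConfig(
    dimensions = unlist(cfg$dimensions),
    outputDir = cfg$output_dir,
    namespaces = unlist(cfg$namespaces),
    quartileFilter = cfg$quartile_filter %||% TRUE,
    interpretation = cfg$interpretation %||% "distance",
    kMax = cfg$k_max %||% 250L,
    selectedK = cfg$selected_k,
    minClusterSize = cfg$min_cluster_size %||% 5L,
    topK = cfg$top_k %||% 10L,
    queryDiseases = unlist(cfg$query_diseases),
    nameMapPath = cfg$name_map,
    icdMappingPath = cfg$icd_mapping,
    seed = cfg$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble and validate a pipeline configuration
#'
#' @param dimensions named character vector of edge-list TSV paths, one per
#'   data dimension.
#' @param outputDir directory where all outputs are written.
#' @param namespaces optional named character vector of feature namespaces
#'   per dimension.
#' @param quartileFilter drop low-coverage diseases per dimension first?
#' @param interpretation adjacency interpretation for IM comparisons.
#' @param kMax largest Dunn-scan cut.
#' @param selectedK override of the scan-selected cluster count.
#' @param minClusterSize smallest cluster reported in enrichment outputs.
#' @param topK neighborhood size for query diseases.
#' @param queryDiseases disease ids to emit neighborhood reports for.
#' @param nameMapPath optional TSV (disease_id, name) used to drop unnamed
#'   diseases.
#' @param icdMappingPath optional TSV (disease_id, ICD-10 code).
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return config list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(dimensions, outputDir, namespaces = NULL,
                           quartileFilter = TRUE,
                           interpretation = "distance",
                           kMax = 250L, selectedK = NULL,
                           minClusterSize = 5L, topK = 10L,
                           queryDiseases = NULL,
                           nameMapPath = NULL, icdMappingPath = NULL,
                           seed = 1L) {
  if (is.null(names(dimensions)) || any(!nzchar(names(dimensions))))
    stop("'dimensions' must be a named vector of file paths")
  missing <- dimensions[!file.exists(dimensions)]
  if (length(missing))
    stop("dimension file(s) not found: ", paste(missing, collapse = ", "))
  for (p in c(nameMapPath, icdMappingPath))
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  if (kMax < 2L) stop("k_max must be >= 2")
  ns <- vapply(names(dimensions), function(dn)
    if (!is.null(namespaces) && dn %in% names(namespaces)) namespaces[[dn]]
    else if (dn %in% names(.dimNamespaces)) .dimNamespaces[[dn]]
    else "chemical", "")
  structure(
    list(dimensions = dimensions, outputDir = outputDir, namespaces = ns,
         quartileFilter = isTRUE(quartileFilter),
         interpretation = match.arg(interpretation,
                                    c("distance", "similarity")),
         kMax = as.integer(kMax),
         selectedK = if (is.null(selectedK)) NULL else as.integer(selectedK),
         minClusterSize = as.integer(minClusterSize),
         topK = as.integer(topK),
         queryDiseases = queryDiseases,
         nameMapPath = nameMapPath, icdMappingPath = icdMappingPath,
         seed = as.integer(seed)),
    class = "PipelineConfig"
  )
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  path
}

#' Run the full multi-dimensional disease-mapping pipeline
#'
#' Reads the per-dimension edge lists, applies the lower-quartile coverage
#' filter (optional), intersects the disease sets (and drops unnamed
#' diseases when a name map is given), computes the six metric matrices and
#' their IM-guided consensus per dimension, fuses the dimensions into the
#' global consensus map, clusters the diseases (ward.D2) with a Dunn-index
#' scan, embeds them by classical MDS, runs one-vs-all enrichment for every
#' reported cluster in every dimension, emits neighborhood reports for the
#' configured query diseases, optionally compares against ICD-10, and writes
#' a JSON run manifest (gamma, weights, config) that makes the run
#' reproducible.
#'
#' @param config a [pipelineConfig()] or [readPipelineConfig()] result.
#' @return the output directory, invisibly; outputs are TSV/JSON/Newick
#'   files under it.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$outputDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  tables <- step("load", {
    tabs <- lapply(names(config$dimensions), function(dn)
      readAssociationTable(config$dimensions[[dn]], dn,
                           config$namespaces[[dn]]))
    names(tabs) <- names(config$dimensions)
    tabs
  })
  incs <- lapply(tables, toIncidence)

  summaries <- NULL
  if (config$quartileFilter) {
    filtered <- step("quartile_filter", lapply(incs, filterLowCoverage))
    incs <- lapply(filtered, `[[`, "incidence")
    summaries <- do.call(rbind, lapply(filtered, `[[`, "summary"))
    .writeTsv(summaries, file.path(out, "coverage_summary.tsv"))
  }

  incs <- step("intersect", intersectDiseases(incs))
  if (!is.null(config$nameMapPath)) {
    nm <- utils::read.delim(config$nameMapPath, header = FALSE,
                            comment.char = "#", stringsAsFactors = FALSE)
    nameMap <- stats::setNames(as.character(nm[[2L]]), as.character(nm[[1L]]))
    incs <- step("exclude_unnamed", excludeUnnamed(incs, nameMap))
  }
  n <- nDiseases(incs[[1L]])
  gamma <- step("gamma_calibration", calibrateGamma(n))

  dimCons <- step("metric_consensus", {
    lapply(names(incs), function(dn) {
      mm <- metricMatrices(incs[[dn]])
      for (m in names(mm))
        writeDistanceMatrix(mm[[m]],
                            file.path(out, sprintf("dist_%s_%s.tsv", dn, m)))
      cons <- .fuseFamily(mm, gamma, config$interpretation)
      writeDistanceMatrix(cons, file.path(out, sprintf("consensus_%s.tsv", dn)))
      cons
    })
  })
  names(dimCons) <- names(incs)

  consensus <- step("dimension_consensus",
                    dimensionConsensus(dimCons, gamma = gamma,
                                       interpretation = config$interpretation))
  writeDistanceMatrix(consensus, file.path(out, "consensus_global.tsv"))
  writeScheduleNewick(mergeSchedule(consensus),
                      file.path(out, "dimension_dendrogram.nwk"))
  writeConsensusProvenance(consensus, file.path(out, "consensus_provenance.json"))
  famDimension <- attr(consensus, "familyDistance")
  .writeTsv(data.frame(dimension = rownames(famDimension), famDimension,
                       check.names = FALSE),
            file.path(out, "dimension_family_distance.tsv"))

  tree <- step("clustering", hclustWard2(consensus))
  writeScheduleNewick(tree, file.path(out, "disease_dendrogram.nwk"))
  scan <- step("dunn_scan", dunnScan(consensus, tree, kMax = config$kMax))
  .writeTsv(scan, file.path(out, "dunn_scan.tsv"))
  selectedK <- config$selectedK %||% attr(scan, "selected_k")
  if (is.na(selectedK))
    stop("pipeline stage 'dunn_scan' found no local maximum; ",
         "set selected_k explicitly")
  labels <- cutK(tree, selectedK)
  .writeTsv(data.frame(disease_id = names(labels), cluster = labels),
            file.path(out, "cluster_assignments.tsv"))

  coords <- step("mds", classicalMds(consensus, dims = 2L))
  .writeTsv(data.frame(disease_id = rownames(coords),
                       mds1 = coords[, 1L], mds2 = coords[, 2L]),
            file.path(out, "mds_coordinates.tsv"))

  step("enrichment", {
    keepCl <- as.integer(names(which(base::table(labels) >=
                                       config$minClusterSize)))
    for (dn in names(incs)) {
      recs <- lapply(keepCl, function(cl)
        fisherOneVsAll(incs[[dn]], labels, cl,
                       nClusters = selectedK,
                       nFeatures = nFeatures(incs[[dn]])))
      if (length(recs))
        .writeTsv(do.call(rbind, recs),
                  file.path(out, sprintf("enrichment_%s.tsv", dn)))
    }
  })

  if (length(config$queryDiseases))
    step("neighborhoods", {
      for (q in config$queryDiseases)
        .writeTsv(topKNeighbors(consensus, q, k = config$topK),
                  file.path(out, sprintf("neighbors_%s.tsv", q)))
    })

  icdGamma <- NULL
  if (!is.null(config$icdMappingPath)) {
    fam <- step("icd_compare", {
      mapping <- readIcdMapping(config$icdMappingPath)
      icdCompare(c(dimCons, list(consensus = consensus)), mapping,
                 interpretation = config$interpretation)
    })
    icdGamma <- attr(fam, "gamma")
    .writeTsv(data.frame(matrix_label = rownames(fam), fam,
                         check.names = FALSE),
              file.path(out, "icd_family_distance.tsv"))
  }

  manifest <- list(
    package = "diseaseMapper",
    version = as.character(utils::packageVersion("diseaseMapper")),
    config = unclass(config),
    n_diseases = n,
    gamma = gamma,
    icd_gamma = icdGamma,
    selected_k = selectedK,
    dimension_weights = as.list(leafWeights(consensus))
  )
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
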