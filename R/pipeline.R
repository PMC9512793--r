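#' @include io.R filtering.R epidemiology.R prevalence.R
NULL

#' Read a pipeline run configuration from YAML
#'
#' The configuration names the input files (cohort MAFs with subtype codes
#' and optional annotation TSVs, gene panel, synonym table, incidence
#' table, subtype-to-site map), the output directory, and the tunable
#' parameters (\code{n_reps}, \code{seed}, \code{top_k}, \code{delta}).
#'
#' @param path YAML file.
#' @return the configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  ## relative paths are taken relative to the config file's directory
  base <- dirname(normalizePath(path))
  abs <- function(p) if (is.null(p) || grepl("^/", p)) p
                     else file.path(base, p)
  for (f in c("panel", "synonyms", "incidence", "site_map"))
    cfg[[f]] <- abs(cfg[[f]])
  cfg$profiles <- lapply(cfg$profiles, function(pr) {
    pr$maf <- abs(pr$maf); pr$annotation <- abs(pr$annotation); pr
  })
  if (!is.null(cfg$out_dir)) cfg$out_dir <- abs(cfg$out_dir)
  cfg
}

#' Validate a run configuration before any computation
#'
#' @param config configuration list (see \code{\link{readRunConfig}}).
#' @return the config, invisibly; errors name the first offending entry.
#' @export
validateRunConfig <- function(config) {
  need <- c("profiles", "panel", "incidence", "site_map", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config is missing entries: ", paste(miss, collapse = ", "))
  paths <- c(config$panel, config$synonyms, config$incidence,
             config$site_map,
             unlist(lapply(config$profiles, function(p)
               c(p$maf, p$annotation))))
  bad <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(bad))
    stop("config references missing files: ", paste(bad, collapse = ", "))
  for (pr in config$profiles)
    if (is.null(pr$subtype)) stop("a profile entry lacks a subtype code")
  invisible(config)
}

.param <- function(config, name, default) {
  v <- config$params[[name]]
  if (is.null(v)) default else v
}

#' Run the full weighted-prevalence pipeline
#'
#' Executes read, synonym resolution, tier-1/tier-2 filtering, per-site
#' aggregation, tabulation, incidence weighting with coverage rescaling,
#' conditional-matrix construction, weighted proportions and the Poisson
#' bootstrap, persisting every intermediate under \code{config$out_dir}
#' together with a stage log (record counts in/out) and a JSON run
#' manifest (seed, replicate count, Q, stage counts).
#'
#' @param config configuration list or path to a YAML config.
#' @return invisibly, a list with \code{prevalence} (the CI table),
#'   \code{matrix}, \code{weights}, \code{tables}, \code{topk} and
#'   \code{manifest}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  validateRunConfig(config)
  outDir <- config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- .param(config, "seed", 1L)
  nReps <- .param(config, "n_reps", 2000L)
  topK <- .param(config, "top_k", 50L)
  logLines <- character()
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    logLines <<- c(logLines, line)
  }

  panel <- readPanel(config$panel, config$synonyms)
  note("panel: ", length(panelGenes(panel)), " genes, ",
       length(synonymMap(panel)), " synonyms")
  siteMap <- readSiteMap(config$site_map)
  incidence <- readIncidence(config$incidence)

  stageCounts <- list()
  cohorts <- lapply(config$profiles, function(pr) {
    co <- readCohort(pr$maf, pr$annotation, cohortId = pr$subtype,
                     subtype = pr$subtype)
    nIn <- nrow(mutationRecords(co))
    co <- resolveSynonyms(co, panel)
    co1 <- tier1Filter(co, panel)
    co2 <- tier2Filter(co1)
    stageCounts[[pr$subtype]] <<- c(read = nIn,
      tier1 = nrow(mutationRecords(co1)),
      tier2 = nrow(mutationRecords(co2)))
    note("cohort ", pr$subtype, ": ", nIn, " records in, ",
         nrow(mutationRecords(co1)), " after tier-1, ",
         nrow(mutationRecords(co2)), " after tier-2")
    co2
  })

  bySite <- aggregateProfiles(cohorts, siteMap)
  note("aggregated ", length(cohorts), " subtype cohorts into ",
       length(bySite), " site cohorts (",
       sum(vapply(bySite, nSamples, integer(1))), " samples)")
  tables <- lapply(bySite, tabulateCohort)

  prelim <- preliminaryWeights(incidence)
  weights <- rescaleForCoverage(prelim, names(bySite))
  note("weights: Q = ", format(qValue(weights), digits = 6), " over ",
       length(siteWeights(weights)), " sequenced sites")

  mat <- conditionalMatrix(tables, panel)
  prev <- poissonCI(mat, weights, nReps = nReps, seed = seed)
  topk <- rankTopK(stats::setNames(prev$estimate, prev$gene), k = topK)

  ## persist intermediates
  utils::write.table(
    data.frame(site = names(preliminaryWeightsOf(weights)),
               preliminary = unname(preliminaryWeightsOf(weights)),
               final = unname(siteWeights(weights)[
                 names(preliminaryWeightsOf(weights))])),
    file.path(outDir, "weights.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(mutCounts(mat)),
                                mutCounts(mat), check.names = FALSE),
                     file.path(outDir, "matrix_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(prev, file.path(outDir, "prevalence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(topk, file.path(outDir, "top_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(seed = seed, n_reps = nReps, top_k = topK,
                   q_value = qValue(weights),
                   n_sites = length(bySite),
                   n_samples = sum(vapply(bySite, nSamples, integer(1))),
                   n_panel_genes = length(panelGenes(panel)),
                   stage_counts = stageCounts)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(logLines, file.path(outDir, "pipeline.log"))
  invisible(list(prevalence = prev, matrix = mat, weights = weights,
                 tables = tables, topk = topk, manifest = manifest))
}
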