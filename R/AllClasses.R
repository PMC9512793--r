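#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

#' Controlled vocabulary of variant consequence classes
#'
#' \code{"other"} is the catch-all assigned at read time to unmapped
#' tokens, so filtering decisions stay centralised in the filtering step.
#' @format character vector
#' @export
VARIANT_CLASSES <- c("missense", "nonsense", "frameshift", "inframe_indel",
                     "splice", "silent", "noncoding", "SV", "fusion", "other")

#' Protein-altering classes retained by tier-2 filtering
#'
#' Frameshift events are kept under the truncating umbrella by default;
#' override via \code{tier2Filter(retain = ...)} for sensitivity analysis.
#' @format character vector
#' @export
PROTEIN_ALTERING <- c("missense", "nonsense", "frameshift", "inframe_indel",
                      "splice")

RECORD_COLUMNS <- c("sample_id", "gene", "variant_class", "chrom", "pos",
                    "ref", "alt", "protein_change")

#' Cancer gene census panel with synonym map
#'
#' Holds the official symbols used for tier-1 filtering plus an alias ->
#' official lookup used to canonicalise gene names before filtering.
#'
#' @slot genes character vector of official symbols (unique).
#' @slot synonyms named character vector; names are aliases, values the
#'   official symbol each alias resolves to. An alias may not map to two
#'   different targets.
#' @exportClass GenePanel
setClass("GenePanel",
  representation(genes = "character", synonyms = "character"))

setValidity("GenePanel", function(object) {
  msg <- character()
  if (length(object@genes) == 0L)
    msg <- c(msg, "panel must contain at least one gene")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "panel gene symbols must be unique")
  syn <- object@synonyms
  if (length(syn)) {
    if (is.null(names(syn)) || any(!nzchar(names(syn))))
      msg <- c(msg, "synonyms must be a named character vector (alias -> official)")
    else if (anyDuplicated(names(syn)))
      msg <- c(msg, "an alias maps to more than one official symbol")
    if (any(names(syn) %in% syn))
      msg <- c(msg, "an alias may not itself be a synonym target (chains/self-maps)")
  }
  if (length(msg)) msg else TRUE
})

#' A named cancer cohort: sample roster plus mutation records
#'
#' The cohort is the unit of tabulation: per-gene mutated-sample fractions
#' are computed within a cohort and later combined across anatomical sites.
#'
#' @slot cohortId cohort label, e.g. "LUAD_CN".
#' @slot subtype detailed subtype code used for site aggregation.
#' @slot site optional ICD-10-style major site code (NA until aggregated).
#' @slot samples data.frame roster with columns sample_id, gender, smoking.
#' @slot records data.frame of mutation calls (one row per call) with columns
#'   sample_id, gene, variant_class, chrom, pos, ref, alt, protein_change.
#' @slot metadata free-form list (e.g. provenance, simulation bookkeeping).
#' @exportClass CohortProfile
setClass("CohortProfile",
  representation(cohortId = "character", subtype = "character",
                 site = "character", samples = "data.frame",
                 records = "data.frame", metadata = "list"))

setValidity("CohortProfile", function(object) {
  msg <- character()
  if (length(object@cohortId) != 1L)
    msg <- c(msg, "cohortId must be a single string")
  if (!"sample_id" %in% names(object@samples))
    msg <- c(msg, "sample roster must have a sample_id column")
  else {
    if (anyDuplicated(object@samples$sample_id))
      msg <- c(msg, "sample roster ids must be unique")
    if (nrow(object@records)) {
      missing <- setdiff(object@records$sample_id, object@samples$sample_id)
      if (length(missing))
        msg <- c(msg, paste0("records reference sample ids outside the roster: ",
                             paste(utils::head(missing, 5L), collapse = ", ")))
    }
  }
  bad <- setdiff(RECORD_COLUMNS, names(object@records))
  if (length(bad))
    msg <- c(msg, paste0("records missing columns: ", paste(bad, collapse = ", ")))
  else if (nrow(object@records)) {
    if (any(!object@records$variant_class %in% VARIANT_CLASSES))
      msg <- c(msg, "records contain variant_class outside the controlled vocabulary")
    if (any(object@records$pos < 1L))
      msg <- c(msg, "positions must be 1-based (pos >= 1)")
  }
  if (length(msg)) msg else TRUE
})

#' Per-cohort gene tabulation (at most one count per sample per gene)
#'
#' @slot cohortId cohort the tabulation came from.
#' @slot N cohort sample count (denominator for mutation proportions).
#' @slot mutated named list: gene -> character vector of mutated sample ids
#'   (deduplicated, so a gene counts at most once per sample).
#' @slot recordCounts named integer: gene -> total qualifying record count
#'   (not deduplicated; used for accumulated mutation rates).
#' @exportClass GeneSampleTable
setClass("GeneSampleTable",
  representation(cohortId = "character", N = "integer",
                 mutated = "list", recordCounts = "integer"))

setValidity("GeneSampleTable", function(object) {
  msg <- character()
  if (object@N < 1L)
    msg <- c(msg, "cohort sample count N must be >= 1")
  ns <- vapply(object@mutated, length, integer(1))
  if (any(ns > object@N))
    msg <- c(msg, "a gene cannot be mutated in more samples than the cohort holds")
  if (!identical(sort(names(object@mutated)), sort(names(object@recordCounts))))
    msg <- c(msg, "mutated and recordCounts must cover the same genes")
  else if (length(ns) && any(object@recordCounts[names(object@mutated)] < ns))
    msg <- c(msg, "record counts cannot be below deduplicated sample counts")
  if (length(msg)) msg else TRUE
})

#' Epidemiological site weight vector
#'
#' Preliminary weights are incidence fractions over all registry sites;
#' final weights renormalise over the sites with sequencing data by dividing
#' by (1 - Q), where Q is the incidence mass of unsequenced sites.
#'
#' @slot weights named numeric, final weights over sequenced sites (sum 1).
#' @slot preliminary named numeric, incidence fractions over all sites.
#' @slot Q numeric in [0, 1): incidence fraction lacking sequencing data.
#' @slot rescaled logical: TRUE once coverage rescaling has been applied.
#' @exportClass WeightVector
setClass("WeightVector",
  representation(weights = "numeric", preliminary = "numeric",
                 Q = "numeric", rescaled = "logical"))

setValidity("WeightVector", function(object) {
  msg <- character()
  tol <- 1e-9
  if (is.null(names(object@weights)) || anyDuplicated(names(object@weights)))
    msg <- c(msg, "weights must be uniquely named by site code")
  if (any(object@weights < 0) || any(object@preliminary < 0))
    msg <- c(msg, "weights must be nonnegative")
  if (length(object@preliminary) &&
      abs(sum(object@preliminary) - 1) > tol)
    msg <- c(msg, "preliminary weights must sum to 1")
  if (abs(sum(object@weights) - 1) > tol)
    msg <- c(msg, "final weights must sum to 1")
  if (object@Q < 0 || object@Q >= 1)
    msg <- c(msg, "Q must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Gene-by-site conditional mutation probability matrix
#'
#' A \linkS4class{SummarizedExperiment} with genes as rows and cancer sites
#' as columns. Assay \code{count} holds mutated-sample counts (each sample
#' counted at most once per gene), assay \code{prob} the conditional
#' probabilities count/N, and \code{colData()$N} the per-site cohort sizes.
#'
#' @exportClass ConditionalMatrix
setClass("ConditionalMatrix", contains = "SummarizedExperiment")

setValidity("ConditionalMatrix", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("count", "prob") %in% an))
    return("assays 'count' and 'prob' are required")
  if (!"N" %in% names(SummarizedExperiment::colData(object)))
    return("colData must carry the per-site cohort size N")
  N <- object$N
  cnt <- SummarizedExperiment::assay(object, "count")
  prob <- SummarizedExperiment::assay(object, "prob")
  if (any(N < 1L))
    msg <- c(msg, "every site cohort size N must be >= 1")
  if (any(cnt < 0) || any(sweep(cnt, 2L, N, `>`)))
    msg <- c(msg, "counts must lie in [0, N] per site")
  if (max(abs(prob - sweep(cnt, 2L, N, `/`))) > 1e-12)
    msg <- c(msg, "prob must equal count / N")
  if (length(msg)) msg else TRUE
})

#' Ground-truth model for synthetic cohorts
#'
#' Defines the generative conditions every downstream stage is checked
#' against: per-site per-gene mutation probabilities, site incidence counts
#' (possibly including sites with no sequencing cohort, to exercise the
#' coverage rescaling), and nuisance rates for noise records and synonym
#' aliasing.
#'
#' @slot genes official gene symbols (row names of \code{prob}).
#' @slot sites ICD-10-like site codes (column names of \code{prob}).
#' @slot prob genes x sites matrix of true mutation probabilities in [0,1].
#' @slot incidence named nonnegative counts per site; may contain extra
#'   sites absent from \code{sites} (no sequencing data).
#' @slot noise fraction of generated records that are non-qualifying.
#' @slot aliasRate fraction of gene symbols emitted as synonyms.
#' @slot lambdaExtra Poisson mean of extra records per mutated sample-gene
#'   pair (so accumulated rates can exceed prevalence).
#' @slot seed integer seed the model was generated from.
#' @exportClass MutationTruth
setClass("MutationTruth",
  representation(genes = "character", sites = "character", prob = "matrix",
                 incidence = "numeric", noise = "numeric",
                 aliasRate = "numeric", lambdaExtra = "numeric",
                 seed = "integer"))

setValidity("MutationTruth", function(object) {
  msg <- character()
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene symbols must be unique")
  if (!identical(dim(object@prob),
                 c(length(object@genes), length(object@sites))))
    msg <- c(msg, "prob matrix must be genes x sites")
  if (any(object@prob < 0) || any(object@prob > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (any(object@incidence < 0))
    msg <- c(msg, "incidence counts must be nonnegative")
  if (!all(object@sites %in% names(object@incidence)))
    msg <- c(msg, "incidence must cover every sequenced site")
  for (fld in c("noise", "aliasRate")) {
    v <- slot(object, fld)
    if (v < 0 || v > 1) msg <- c(msg, paste0(fld, " must lie in [0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

#' Per-caller gene-to-patient call set
#'
#' @slot callerId caller label, e.g. "mutect2".
#' @slot calls named list: gene -> character vector of patient ids with at
#'   least one qualifying call (deduplicated).
#' @exportClass CallerCallSet
setClass("CallerCallSet",
  representation(callerId = "character", calls = "list"))

setValidity("CallerCallSet", function(object) {
  msg <- character()
  if (length(object@callerId) != 1L)
    msg <- c(msg, "callerId must be a single string")
  if (length(object@calls) && is.null(names(object@calls)))
    msg <- c(msg, "calls must be named by gene")
  if (any(vapply(object@calls, anyDuplicated, integer(1)) > 0L))
    msg <- c(msg, "patient sets must be deduplicated")
  if (length(msg)) msg else TRUE
})
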