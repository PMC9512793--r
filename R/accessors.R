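#' @include AllGenerics.R
NULL

#' Construct a gene panel
#'
#' @param genes character vector of official symbols.
#' @param synonyms named character vector mapping alias -> official symbol,
#'   or a two-column data.frame (alias, official).
#' @return A \linkS4class{GenePanel}.
#' @examples
#' panel <- GenePanel(c("TP53", "EGFR"), c(P53 = "TP53", ERBB1 = "EGFR"))
#' panelGenes(panel)
#' @export
GenePanel <- function(genes, synonyms = character()) {
  if (is.data.frame(synonyms)) {
    stopifnot(ncol(synonyms) >= 2L)
    synonyms <- stats::setNames(as.character(synonyms[[2L]]),
                                as.character(synonyms[[1L]]))
  }
  new("GenePanel", genes = unique(as.character(genes)),
      synonyms = synonyms)
}

#' Construct a cohort profile
#'
#' @param cohortId cohort label.
#' @param samples roster data.frame (column \code{sample_id}; optional
#'   \code{gender}, \code{smoking}) or a character vector of sample ids.
#' @param records mutation record data.frame (see
#'   \linkS4class{CohortProfile}); defaults to an empty record set.
#' @param subtype detailed subtype code.
#' @param site ICD-10-style major site code, if already known.
#' @param metadata free-form list.
#' @return A \linkS4class{CohortProfile}.
#' @export
CohortProfile <- function(cohortId, samples, records = emptyRecords(),
                          subtype = cohortId, site = NA_character_,
                          metadata = list()) {
  if (is.character(samples))
    samples <- data.frame(sample_id = samples)
  if (!"gender" %in% names(samples))
    samples$gender <- rep("unknown", nrow(samples))
  if (!"smoking" %in% names(samples))
    samples$smoking <- rep("unknown", nrow(samples))
  rownames(samples) <- NULL
  rownames(records) <- NULL
  new("CohortProfile", cohortId = as.character(cohortId),
      subtype = as.character(subtype), site = as.character(site),
      samples = samples, records = records[RECORD_COLUMNS],
      metadata = metadata)
}

#' Empty mutation record table with the canonical columns
#' @return zero-row data.frame with the record schema.
#' @export
emptyRecords <- function() {
  data.frame(sample_id = character(), gene = character(),
             variant_class = character(), chrom = character(),
             pos = integer(), ref = character(), alt = character(),
             protein_change = character())
}

#' @describeIn CohortProfile cohort label
#' @param x a CohortProfile
#' @export
setMethod("cohortId", "CohortProfile", function(x) x@cohortId)

#' @describeIn CohortProfile number of samples in the roster
#' @export
setMethod("nSamples", "CohortProfile", function(x) nrow(x@samples))

#' @describeIn CohortProfile the sample roster data.frame
#' @export
setMethod("sampleRoster", "CohortProfile", function(x) x@samples)

#' @describeIn CohortProfile the mutation record data.frame
#' @export
setMethod("mutationRecords", "CohortProfile", function(x) x@records)

#' Replace the records of a cohort (roster unchanged)
#'
#' @param cohort a \linkS4class{CohortProfile}.
#' @param records replacement record data.frame; all sample ids must be in
#'   the roster.
#' @return the updated cohort.
#' @export
setRecords <- function(cohort, records) {
  rownames(records) <- NULL
  cohort@records <- records[RECORD_COLUMNS]
  validObject(cohort)
  cohort
}

#' @describeIn GenePanel official symbols
#' @param x a GenePanel
#' @export
setMethod("panelGenes", "GenePanel", function(x) x@genes)

#' @describeIn GenePanel alias -> official lookup
#' @export
setMethod("synonymMap", "GenePanel", function(x) x@synonyms)

#' @describeIn WeightVector final weights over sequenced sites
#' @param x a WeightVector
#' @export
setMethod("siteWeights", "WeightVector", function(x) x@weights)

#' @describeIn WeightVector preliminary weights over all registry sites
#' @export
setMethod("preliminaryWeightsOf", "WeightVector", function(x) x@preliminary)

#' @describeIn WeightVector incidence fraction without sequencing data
#' @export
setMethod("qValue", "WeightVector", function(x) x@Q)

#' @describeIn GeneSampleTable cohort label
#' @param x a GeneSampleTable
#' @export
setMethod("cohortId", "GeneSampleTable", function(x) x@cohortId)

#' @describeIn GeneSampleTable cohort size N
#' @export
setMethod("nSamples", "GeneSampleTable", function(x) x@N)

#' @describeIn GeneSampleTable mutated sample ids for one gene
#' @param gene gene symbol
#' @export
setMethod("mutatedSamples", "GeneSampleTable", function(x, gene) {
  ids <- x@mutated[[gene]]
  if (is.null(ids)) character() else ids
})

#' @describeIn GeneSampleTable named vector of deduplicated mutated-sample
#'   counts per gene
#' @export
setMethod("mutationCounts", "GeneSampleTable", function(x)
  vapply(x@mutated, length, integer(1)))

#' @describeIn GeneSampleTable named vector of total qualifying record
#'   counts per gene (not deduplicated)
#' @export
setMethod("recordCounts", "GeneSampleTable", function(x) x@recordCounts)

#' @describeIn MutationTruth true gene x site probability matrix
#' @param x a MutationTruth
#' @export
setMethod("trueProb", "MutationTruth", function(x) x@prob)

#' @describeIn MutationTruth true weighted proportion per gene under a
#'   weight vector (the estimand of the whole pipeline)
#' @param weights a \linkS4class{WeightVector} or named numeric over sites
#' @export
setMethod("trueWeighted", "MutationTruth", function(x, weights) {
  w <- if (is(weights, "WeightVector")) siteWeights(weights) else weights
  stopifnot(all(names(w) %in% x@sites))
  drop(x@prob[, names(w), drop = FALSE] %*% w)
})

#' @describeIn CallerCallSet caller label
#' @param x a CallerCallSet
#' @export
setMethod("callerId", "CallerCallSet", function(x) x@callerId)

#' @describeIn CallerCallSet named list gene -> patient ids
#' @export
setMethod("geneCalls", "CallerCallSet", function(x) x@calls)

setMethod("show", "GenePanel", function(object) {
  cat("GenePanel with", length(object@genes), "genes and",
      length(object@synonyms), "synonyms\n")
})

setMethod("show", "CohortProfile", function(object) {
  cat("CohortProfile", object@cohortId,
      sprintf("(subtype %s, site %s)\n", object@subtype, object@site))
  cat("  samples:", nrow(object@samples),
      " records:", nrow(object@records), "\n")
})

setMethod("show", "GeneSampleTable", function(object) {
  cat("GeneSampleTable for", object@cohortId, "- N =", object@N,
      ",", length(object@mutated), "genes\n")
})

setMethod("show", "WeightVector", function(object) {
  cat("WeightVector over", length(object@weights), "sequenced sites",
      sprintf("(Q = %.4f%s)\n", object@Q,
              if (object@rescaled) ", rescaled" else ""))
})

setMethod("show", "MutationTruth", function(object) {
  cat("MutationTruth:", length(object@genes), "genes x",
      length(object@sites), "sites;",
      length(object@incidence) - length(object@sites),
      "unsequenced incidence sites\n")
})

setMethod("show", "CallerCallSet", function(object) {
  cat("CallerCallSet", object@callerId, "-", length(object@calls),
      "genes,", length(unique(unlist(object@calls))), "patients\n")
})
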