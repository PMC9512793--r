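#' @include accessors.R
NULL

.recordsOf <- function(x) if (is(x, "CohortProfile")) mutationRecords(x) else x

.returnLike <- function(x, rec) {
  if (is(x, "CohortProfile")) setRecords(x, rec) else rec
}

#' Tier-1 filter: restrict records to census panel genes
#'
#' Records are kept when their (synonym-resolved) gene symbol belongs to
#' the cancer-gene census panel.
#'
#' @param x record data.frame or \linkS4class{CohortProfile} with synonyms
#'   already resolved.
#' @param panel a \linkS4class{GenePanel}.
#' @return same class as \code{x}, restricted to panel genes.
#' @export
tier1Filter <- function(x, panel) {
  if (length(panelGenes(panel)) == 0L) stop("empty gene panel")
  rec <- .recordsOf(x)
  .returnLike(x, rec[rec$gene %in% panelGenes(panel), , drop = FALSE])
}

#' Tier-2 filter: retain protein-altering consequences only
#'
#' Keeps missense, nonsense (truncating), frameshift, short inframe indel
#' and splice records; silent, noncoding, SV, fusion and unclassified
#' ("other") records are removed. Whether frameshift events count as
#' truncating is configurable for sensitivity analysis.
#'
#' @param x record data.frame or \linkS4class{CohortProfile}.
#' @param retain character vector of retained classes; default
#'   \code{PROTEIN_ALTERING}.
#' @return same class as \code{x}, protein-altering records only.
#' @export
tier2Filter <- function(x, retain = PROTEIN_ALTERING) {
  stopifnot(all(retain %in% VARIANT_CLASSES))
  rec <- .recordsOf(x)
  .returnLike(x, rec[rec$variant_class %in% retain, , drop = FALSE])
}

#' Apply both filtering tiers
#'
#' Order is immaterial (the two predicates act on different fields); tier-1
#' then tier-2 is used, matching the processing narrative.
#'
#' @inheritParams tier1Filter
#' @param retain classes retained by tier 2.
#' @return filtered object of the same class as \code{x}.
#' @export
filterRecords <- function(x, panel, retain = PROTEIN_ALTERING) {
  tier2Filter(tier1Filter(x, panel), retain = retain)
}

#' Collapse duplicate identical records
#'
#' Merged multi-repository studies can carry the same call twice; rows
#' identical on (sample, gene, chrom, pos, ref, alt) are collapsed to one
#' before tabulation.
#'
#' @param x record data.frame or \linkS4class{CohortProfile}.
#' @return deduplicated object of the same class.
#' @export
dedupRecords <- function(x) {
  rec <- .recordsOf(x)
  key <- rec[c("sample_id", "gene", "chrom", "pos", "ref", "alt")]
  .returnLike(x, rec[!duplicated(key), , drop = FALSE])
}

#' Tabulate a cohort: mutated-sample sets per gene
#'
#' A gene is tabulated as mutated at most once per sample regardless of how
#' many records the sample carries; the raw qualifying record totals are
#' kept alongside for accumulated-rate calculations. Records are expected
#' to be two-tier filtered already.
#'
#' @param cohort a \linkS4class{CohortProfile} with at least one sample.
#' @param collapseDuplicates collapse byte-identical calls first (default
#'   TRUE, guarding against merged-study duplication).
#' @return a \linkS4class{GeneSampleTable}.
#' @export
tabulateCohort <- function(cohort, collapseDuplicates = TRUE) {
  if (nSamples(cohort) == 0L)
    stop("cohort ", cohortId(cohort),
         " has no samples; proportions are undefined")
  if (collapseDuplicates) cohort <- dedupRecords(cohort)
  rec <- mutationRecords(cohort)
  if (nrow(rec)) {
    mutated <- lapply(split(rec$sample_id, rec$gene), function(s)
      sort(unique(s)))
    counts <- vapply(split(rec$sample_id, rec$gene), length, integer(1))
  } else {
    mutated <- stats::setNames(list(), character())
    counts <- stats::setNames(integer(), character())
  }
  new("GeneSampleTable", cohortId = cohortId(cohort),
      N = nSamples(cohort), mutated = mutated,
      recordCounts = counts[names(mutated)])
}

#' Stratify a cohort by gender and/or smoking status
#'
#' Restricts roster and records to samples matching the requested strata.
#' Samples annotated "unknown" are excluded from a stratum unless
#' \code{"unknown"} is requested explicitly. An empty result is returned
#' with a warning rather than silently treated as zero signal.
#'
#' @param cohort a \linkS4class{CohortProfile} with annotation joined.
#' @param gender optional, one of "female", "male", "unknown".
#' @param smoking optional, one of "smoker", "non-smoker", "unknown".
#' @return the stratified \linkS4class{CohortProfile}.
#' @export
stratifyCohort <- function(cohort, gender = NULL, smoking = NULL) {
  roster <- sampleRoster(cohort)
  keep <- rep(TRUE, nrow(roster))
  tags <- character()
  if (!is.null(gender)) {
    keep <- keep & roster$gender %in% gender
    tags <- c(tags, paste0("gender=", paste(gender, collapse = "/")))
  }
  if (!is.null(smoking)) {
    keep <- keep & roster$smoking %in% smoking
    tags <- c(tags, paste0("smoking=", paste(smoking, collapse = "/")))
  }
  roster <- roster[keep, , drop = FALSE]
  rec <- mutationRecords(cohort)
  rec <- rec[rec$sample_id %in% roster$sample_id, , drop = FALSE]
  out <- CohortProfile(
    paste(c(cohortId(cohort), tags), collapse = "|"),
    roster, rec, subtype = cohort@subtype, site = cohort@site,
    metadata = cohort@metadata)
  if (nrow(roster) == 0L)
    warning("stratum ", paste(tags, collapse = ", "), " of cohort ",
            cohortId(cohort), " is empty")
  out
}
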