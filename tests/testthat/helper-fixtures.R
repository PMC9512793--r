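# In-code fixtures shared across test files.

# Build a canonical record data.frame from terse per-record triples.
mkRecords <- function(sample_id, gene, variant_class,
                      pos = seq_along(sample_id)) {
  data.frame(sample_id = sample_id, gene = gene,
             variant_class = variant_class,
             chrom = "chr1", pos = as.integer(pos), ref = "A", alt = "T",
             protein_change = NA_character_)
}

mkCohort <- function(id, samples, records = emptyRecords(), ...) {
  CohortProfile(id, samples, records, ...)
}

# Deterministic tiny panel used across io/filtering tests.
tinyPanel <- function() {
  GenePanel(c("TP53", "EGFR", "KRAS"),
            c(P53 = "TP53", ERBB1 = "EGFR"))
}

# Canonical sort so record multisets can be compared after round trips;
# bookkeeping attributes (load report, substitution counts) are dropped.
sortRecords <- function(rec) {
  rec <- rec[do.call(order, rec), ]
  rownames(rec) <- NULL
  attr(rec, "report") <- NULL
  attr(rec, "substitutions") <- NULL
  rec
}

# Independent per-sample brute-force tabulation used as oracle.
bruteTabulate <- function(records) {
  genes <- sort(unique(records$gene))
  out <- list()
  for (g in genes) {
    ids <- character()
    for (i in seq_len(nrow(records)))
      if (records$gene[i] == g) ids <- c(ids, records$sample_id[i])
    out[[g]] <- sort(unique(ids))
  }
  out
}
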