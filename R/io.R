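#' @include accessors.R
NULL

## Default mapping from MAF-style Variant_Classification tokens to the
## controlled vocabulary. Mirrors the cBioPortal/TCGA MAF vocabulary; rows
## not covered here are mapped to "other" and counted in the load report.
## Shipped as inst/extdata/variant_class_map.tsv so users can extend it.
.defaultClassMap <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "nonsense",
  Frame_Shift_Del   = "frameshift",
  Frame_Shift_Ins   = "frameshift",
  In_Frame_Del      = "inframe_indel",
  In_Frame_Ins      = "inframe_indel",
  Splice_Site       = "splice",
  Splice_Region     = "splice",
  Silent            = "silent",
  `3'UTR`           = "noncoding",
  `5'UTR`           = "noncoding",
  `3'Flank`         = "noncoding",
  `5'Flank`         = "noncoding",
  Intron            = "noncoding",
  IGR               = "noncoding",
  RNA               = "noncoding",
  lincRNA           = "noncoding",
  Translation_Start_Site = "other",
  Nonstop_Mutation  = "other",
  SV                = "SV",
  Fusion            = "fusion",
  Fusion_Gene       = "fusion")

#' MAF dialect configuration
#'
#' Describes how to map a tab-separated mutation table onto the canonical
#' record schema: which input column feeds each field and how the file's
#' variant-classification vocabulary maps onto the controlled one.
#'
#' @param columns named character vector mapping canonical field names
#'   (\code{sample_id}, \code{gene}, \code{variant_class}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{protein_change}) to input
#'   column headers. \code{protein_change} is optional.
#' @param classMap named character vector mapping the dialect's
#'   variant-classification tokens to the controlled vocabulary
#'   (\code{VARIANT_CLASSES}); tokens not in the map become \code{"other"}.
#' @return a list with elements \code{columns} and \code{classMap}.
#' @examples
#' d <- mafDialect()
#' d$columns[["gene"]]
#' @export
mafDialect <- function(columns = c(
                         sample_id = "Tumor_Sample_Barcode",
                         gene = "Hugo_Symbol",
                         variant_class = "Variant_Classification",
                         chrom = "Chromosome",
                         pos = "Start_Position",
                         ref = "Reference_Allele",
                         alt = "Tumor_Seq_Allele2",
                         protein_change = "HGVSp_Short"),
                       classMap = .defaultClassMap) {
  mandatory <- setdiff(RECORD_COLUMNS, "protein_change")
  missing <- setdiff(mandatory, names(columns))
  if (length(missing))
    stop("dialect does not define input columns for: ",
         paste(missing, collapse = ", "))
  if (any(!classMap %in% VARIANT_CLASSES))
    stop("classMap targets outside the controlled vocabulary")
  list(columns = columns, classMap = classMap)
}

#' Read a MAF-style tab-separated mutation table
#'
#' One \code{MutationRecord} row is produced per data row; the dialect's
#' variant-class vocabulary is mapped to the controlled one, with unmapped
#' tokens retained as \code{"other"} (filtering happens later, in one
#' place). A load report is attached as attribute \code{"report"}.
#'
#' @param path file path.
#' @param dialect a \code{\link{mafDialect}}.
#' @return data.frame of canonical records; attribute \code{report} is a
#'   list with \code{n_rows}, \code{n_other} (rows whose class token was
#'   unmapped) and \code{unknown_tokens}.
#' @export
readMaf <- function(path, dialect = mafDialect()) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#",
                           colClasses = "character", na.strings = NULL)
  cols <- dialect$columns
  mandatory <- setdiff(RECORD_COLUMNS, "protein_change")
  absent <- setdiff(cols[mandatory], names(raw))
  if (length(absent))
    stop("mandatory column(s) missing from ", path, ": ",
         paste(absent, collapse = ", "))
  getcol <- function(field, default = NA_character_) {
    nm <- if (field %in% names(cols)) cols[[field]] else NULL
    if (!is.null(nm) && nm %in% names(raw)) as.character(raw[[nm]])
    else rep(default, nrow(raw))
  }
  tokens <- getcol("variant_class")
  mapped <- unname(dialect$classMap[tokens])
  unknown <- unique(tokens[is.na(mapped) & !is.na(tokens)])
  mapped[is.na(mapped)] <- "other"
  rec <- data.frame(
    sample_id = getcol("sample_id"),
    gene = getcol("gene"),
    variant_class = mapped,
    chrom = getcol("chrom"),
    pos = as.integer(getcol("pos")),
    ref = getcol("ref"),
    alt = getcol("alt"),
    protein_change = getcol("protein_change"))
  rec$protein_change[!is.na(rec$protein_change) &
                       !nzchar(rec$protein_change)] <- NA_character_
  attr(rec, "report") <- list(n_rows = nrow(rec),
                              n_other = sum(mapped == "other"),
                              unknown_tokens = unknown)
  rec
}

#' Write mutation records as a MAF-style table
#'
#' Inverse of \code{\link{readMaf}} for the same dialect: reading the file
#' back reproduces the records up to column order. Controlled-vocabulary
#' classes are rendered through the first dialect token mapping to each
#' class (classes without a token, e.g. "other", are written verbatim).
#'
#' @param x a \linkS4class{CohortProfile} or a canonical record data.frame.
#' @param path output path.
#' @param dialect a \code{\link{mafDialect}}.
#' @return the path, invisibly.
#' @export
writeMaf <- function(x, path, dialect = mafDialect()) {
  rec <- if (is(x, "CohortProfile")) mutationRecords(x) else x
  inv <- names(dialect$classMap)[match(rec$variant_class, dialect$classMap)]
  inv[is.na(inv)] <- rec$variant_class[is.na(inv)]
  out <- data.frame(rec$sample_id, rec$gene, inv, rec$chrom, rec$pos,
                    rec$ref, rec$alt, rec$protein_change,
                    check.names = FALSE)
  names(out) <- dialect$columns[RECORD_COLUMNS]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a cohort's sample annotation table
#'
#' @param cohort a \linkS4class{CohortProfile}.
#' @param path output path for the TSV (sample_id, gender, smoking).
#' @return the path, invisibly.
#' @export
writeSampleAnnotation <- function(cohort, path) {
  utils::write.table(sampleRoster(cohort), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Missing gender/smoking values become \code{"unknown"}, mirroring
#' clinical-file conventions where absence of an attribute is not an error.
#'
#' @param path TSV with a \code{sample_id} column and optional
#'   \code{gender} and \code{smoking} columns.
#' @return roster data.frame.
#' @export
readSampleAnnotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(ann))
    stop("annotation file lacks a sample_id column: ", path)
  for (col in c("gender", "smoking")) {
    if (!col %in% names(ann)) ann[[col]] <- "unknown"
    ann[[col]][is.na(ann[[col]]) | !nzchar(ann[[col]])] <- "unknown"
  }
  ann[c("sample_id", "gender", "smoking")]
}

#' Read a cohort (MAF + optional annotation) from disk
#'
#' @param mafPath MAF-style records file.
#' @param annotationPath optional sample annotation TSV; when absent the
#'   roster is taken from the sample ids observed in the records.
#' @param cohortId,subtype,site cohort labels.
#' @param dialect a \code{\link{mafDialect}}.
#' @return a \linkS4class{CohortProfile}.
#' @export
readCohort <- function(mafPath, annotationPath = NULL,
                       cohortId = basename(mafPath), subtype = cohortId,
                       site = NA_character_, dialect = mafDialect()) {
  rec <- readMaf(mafPath, dialect)
  roster <- if (is.null(annotationPath))
    data.frame(sample_id = unique(rec$sample_id))
  else readSampleAnnotation(annotationPath)
  CohortProfile(cohortId, roster, rec, subtype = subtype, site = site,
                metadata = list(load_report = attr(rec, "report")))
}

#' Read a gene panel (and optional synonym table)
#'
#' @param genesPath text file whose first column holds official symbols
#'   (header optional, detected via the literal "gene" header).
#' @param synonymsPath optional two-column TSV (alias, official). An alias
#'   mapping to two different targets is a configuration error.
#' @return a \linkS4class{GenePanel}.
#' @export
readPanel <- function(genesPath, synonymsPath = NULL) {
  g <- utils::read.delim(genesPath, stringsAsFactors = FALSE,
                         header = FALSE)[[1L]]
  g <- g[nzchar(g)]
  if (length(g) && tolower(g[1L]) %in% c("gene", "symbol", "hugo_symbol"))
    g <- g[-1L]
  syn <- character()
  if (!is.null(synonymsPath)) {
    s <- utils::read.delim(synonymsPath, stringsAsFactors = FALSE)
    if (ncol(s) < 2L) stop("synonym table needs two columns (alias, official)")
    dup <- unique(s[[1L]][duplicated(s[[1L]])])
    if (length(dup)) {
      tgt <- tapply(s[[2L]], s[[1L]], function(v) length(unique(v)))
      amb <- names(tgt)[tgt > 1L]
      if (length(amb))
        stop("ambiguous synonym mapping for: ", paste(amb, collapse = ", "))
      s <- s[!duplicated(s[[1L]]), ]
    }
    syn <- stats::setNames(as.character(s[[2L]]), as.character(s[[1L]]))
  }
  GenePanel(g, syn)
}

#' Resolve gene synonyms to official symbols
#'
#' Records whose gene symbol is a known alias are rewritten to the official
#' symbol; the operation is idempotent (aliases cannot chain). The number of
#' substitutions is attached as attribute \code{"substitutions"}.
#'
#' @param x canonical record data.frame or a \linkS4class{CohortProfile}.
#' @param panel a \linkS4class{GenePanel} carrying the synonym map.
#' @return object of the same class as \code{x} with canonical symbols.
#' @export
resolveSynonyms <- function(x, panel) {
  if (is(x, "CohortProfile")) {
    rec <- resolveSynonyms(mutationRecords(x), panel)
    out <- setRecords(x, rec)
    out@metadata$synonym_substitutions <- attr(rec, "substitutions")
    return(out)
  }
  syn <- synonymMap(panel)
  hit <- x$gene %in% names(syn)
  x$gene[hit] <- unname(syn[x$gene[hit]])
  attr(x, "substitutions") <- sum(hit)
  x
}

#' Read an incidence table
#'
#' @param path TSV with columns \code{site}, \code{year}, \code{cases}.
#' @return validated data.frame.
#' @export
readIncidence <- function(path) {
  inc <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("site", "year", "cases")
  if (!all(need %in% names(inc)))
    stop("incidence table needs columns: ", paste(need, collapse = ", "))
  if (any(inc$cases < 0)) stop("incidence cases must be nonnegative")
  if (anyDuplicated(inc[c("site", "year")]))
    stop("duplicate (site, year) rows in incidence table")
  inc[need]
}

#' Read a subtype-to-site map
#'
#' @param path two-column TSV (subtype or ICD-O-3 category, ICD-10 site).
#' @return named character vector: subtype -> site.
#' @export
readSiteMap <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(m) < 2L) stop("site map needs two columns (subtype, site)")
  if (anyDuplicated(m[[1L]]))
    stop("site map is not many-to-one: duplicated subtype codes")
  stats::setNames(as.character(m[[2L]]), as.character(m[[1L]]))
}
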