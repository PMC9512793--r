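#' @include accessors.R
NULL

.AMINO <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
.BASES <- c("A", "C", "G", "T")

#' Generate a ground-truth model for synthetic cohorts
#'
#' Per-site per-gene mutation probabilities are drawn from a two-component
#' mixture: with probability 0.7 a near-zero Beta(1.2, 30) draw and with
#' probability 0.3 a Beta(2, 6) draw, so that a handful of genes reach high
#' rates against a sparse background. The first gene is named TP53 and its
#' row is drawn from Beta(8, 6), mimicking the dominance of TP53 in real
#' pan-cancer profiles. Incidence counts are drawn per site (including
#' \code{nUnsequenced} extra sites with no sequencing cohort, so the
#' coverage gap Q is exercised downstream).
#'
#' @param nGenes,nSites panel and sequenced-site dimensions (>= 1).
#' @param seed integer seed; the same seed reproduces the model exactly.
#' @param nUnsequenced extra incidence-only sites (default 2).
#' @param noise fraction of emitted records that are non-qualifying
#'   (silent/noncoding/SV/fusion or off-panel) (default 0.05).
#' @param aliasRate fraction of gene symbols emitted as synonyms
#'   (default 0.05).
#' @param lambdaExtra Poisson mean of additional records per mutated
#'   sample-gene pair (default 0.15), so accumulated rates exceed
#'   prevalence.
#' @param prob optional genes x sites probability matrix overriding the
#'   mixture draw (dimension-checked); used to pin exact study conditions.
#' @return a \linkS4class{MutationTruth}.
#' @export
simTruth <- function(nGenes, nSites, seed = 1L, nUnsequenced = 2L,
                     noise = 0.05, aliasRate = 0.05, lambdaExtra = 0.15,
                     prob = NULL) {
  if (nGenes < 1L || nSites < 1L)
    stop("nGenes and nSites must be >= 1")
  genes <- c("TP53", sprintf("GEN%03d", seq_len(max(0L, nGenes - 1L))))
  genes <- genes[seq_len(nGenes)]
  sites <- sprintf("C%02d", seq_len(nSites))
  extra <- if (nUnsequenced > 0L)
    sprintf("X%02d", seq_len(nUnsequenced)) else character()
  withSeed(seed, {
    if (is.null(prob)) {
      hot <- stats::rbinom(nGenes * nSites, 1L, 0.3) == 1L
      p <- ifelse(hot, stats::rbeta(nGenes * nSites, 2, 6),
                  stats::rbeta(nGenes * nSites, 1.2, 30))
      prob <- matrix(p, nGenes, nSites)
      prob[1L, ] <- stats::rbeta(nSites, 8, 6)   # TP53-like dominant row
    } else {
      stopifnot(identical(dim(prob),
                          as.integer(c(nGenes, nSites))))
    }
    dimnames(prob) <- list(genes, sites)
    incidence <- stats::setNames(
      pmax(100, round(stats::rgamma(nSites + length(extra),
                                    shape = 2, scale = 5000))),
      c(sites, extra))
    new("MutationTruth", genes = genes, sites = sites, prob = prob,
        incidence = incidence, noise = noise, aliasRate = aliasRate,
        lambdaExtra = lambdaExtra, seed = as.integer(seed))
  })
}

#' Gene panel (with synonym table) implied by a truth model
#'
#' Every truth gene gets one deterministic alias ("SYN_" prefix; TP53 gets
#' the classic "P53"), so aliased records are always resolvable.
#'
#' @param truth a \linkS4class{MutationTruth}.
#' @return a \linkS4class{GenePanel}.
#' @export
truthPanel <- function(truth) {
  aliases <- ifelse(truth@genes == "TP53", "P53",
                    paste0("SYN_", truth@genes))
  GenePanel(truth@genes, stats::setNames(truth@genes, aliases))
}

#' Incidence table implied by a truth model
#'
#' @param truth a \linkS4class{MutationTruth}.
#' @param years calendar years the counts are spread over (default a
#'   single nominal year, since only per-site totals matter for weights).
#' @return data.frame (site, year, cases).
#' @export
truthIncidence <- function(truth, years = 2016L) {
  sites <- names(truth@incidence)
  per <- length(years)
  data.frame(site = rep(sites, each = per), year = rep(years, length(sites)),
             cases = as.vector(vapply(truth@incidence, function(cc) {
               base <- floor(cc / per)
               counts <- rep(base, per)
               counts[per] <- counts[per] + cc - base * per
               counts
             }, numeric(per))))
}

.randomProteinChange <- function(n) {
  sprintf("%s%d%s", sample(.AMINO, n, replace = TRUE),
          sample.int(900L, n, replace = TRUE),
          sample(.AMINO, n, replace = TRUE))
}

.randomRecordFields <- function(n) {
  data.frame(chrom = paste0("chr", sample.int(22L, n, replace = TRUE)),
             pos = sample.int(100000000L, n, replace = TRUE),
             ref = sample(.BASES, n, replace = TRUE),
             alt = sample(.BASES, n, replace = TRUE))
}

#' Generate per-site synthetic cohorts from a truth model
#'
#' Each sample carries, per gene, a Bernoulli(true probability) qualifying
#' mutation indicator; a mutated sample-gene pair emits 1 + Poisson(lambda)
#' records with protein-altering classes. Non-qualifying noise records
#' (silent/noncoding/SV/fusion on panel genes, or off-panel genes) are
#' appended so that they make up the truth model's \code{noise} fraction of
#' all records, and a fraction \code{aliasRate} of gene symbols is emitted
#' as synonyms. Gender is drawn 50/50 and smoking 30/60/10
#' (smoker/non-smoker/unknown). The clean canonical qualifying record set
#' is stored in each cohort's \code{metadata$truth_records} for round-trip
#' checks.
#'
#' @param truth a \linkS4class{MutationTruth}.
#' @param samplesPerSite cohort size per sequenced site (>= 1), recycled
#'   across sites.
#' @param seed integer seed.
#' @return named list of \linkS4class{CohortProfile}s, one per sequenced
#'   site (subtype = site code).
#' @export
simCohorts <- function(truth, samplesPerSite, seed = 1L) {
  stopifnot(all(samplesPerSite >= 1L))
  sizes <- rep_len(as.integer(samplesPerSite), length(truth@sites))
  panel <- truthPanel(truth)
  aliasOf <- stats::setNames(names(synonymMap(panel)),
                             unname(synonymMap(panel)))
  withSeed(seed, {
    cohorts <- lapply(seq_along(truth@sites), function(j) {
      site <- truth@sites[j]
      N <- sizes[j]
      ids <- sprintf("%s_S%05d", site, seq_len(N))
      roster <- data.frame(
        sample_id = ids,
        gender = sample(c("female", "male"), N, replace = TRUE),
        smoking = sample(c("smoker", "non-smoker", "unknown"), N,
                         replace = TRUE, prob = c(0.3, 0.6, 0.1)))
      ## Bernoulli qualifying-mutation indicators, gene-major
      hit <- matrix(stats::runif(length(truth@genes) * N) <
                      truth@prob[, j], nrow = length(truth@genes))
      idx <- which(hit, arr.ind = TRUE)
      if (nrow(idx)) {
        nrec <- 1L + stats::rpois(nrow(idx), truth@lambdaExtra)
        gene <- rep(truth@genes[idx[, 1L]], nrec)
        samp <- rep(ids[idx[, 2L]], nrec)
        cls <- sample(PROTEIN_ALTERING, length(gene), replace = TRUE,
                      prob = c(0.6, 0.15, 0.1, 0.05, 0.1))
        qual <- cbind(data.frame(sample_id = samp, gene = gene,
                                 variant_class = cls),
                      .randomRecordFields(length(gene)))
        qual$protein_change <- ifelse(qual$variant_class == "missense",
                                      .randomProteinChange(nrow(qual)),
                                      NA_character_)
        qual <- qual[RECORD_COLUMNS]
      } else qual <- emptyRecords()
      ## noise records: non-qualifying by class or by off-panel symbol
      nNoise <- if (truth@noise > 0 && nrow(qual) > 0)
        as.integer(round(truth@noise / (1 - truth@noise) * nrow(qual)))
      else 0L
      if (nNoise > 0L) {
        offPanel <- stats::runif(nNoise) < 0.4
        ngene <- ifelse(offPanel,
                        sprintf("NPG%03d", sample.int(50L, nNoise, TRUE)),
                        sample(truth@genes, nNoise, replace = TRUE))
        ncls <- ifelse(offPanel,
                       sample(VARIANT_CLASSES, nNoise, replace = TRUE),
                       sample(c("silent", "noncoding", "SV", "fusion",
                                "other"), nNoise, replace = TRUE))
        noiseRec <- cbind(data.frame(sample_id = sample(ids, nNoise, TRUE),
                                     gene = ngene, variant_class = ncls),
                          .randomRecordFields(nNoise))
        noiseRec$protein_change <- NA_character_
        noiseRec <- noiseRec[RECORD_COLUMNS]
      } else noiseRec <- emptyRecords()
      emitted <- rbind(qual, noiseRec)
      ## alias a fraction of panel-gene symbols (only resolvable aliases)
      canAlias <- emitted$gene %in% names(aliasOf)
      doAlias <- canAlias & stats::runif(nrow(emitted)) < truth@aliasRate
      emitted$gene[doAlias] <- unname(aliasOf[emitted$gene[doAlias]])
      CohortProfile(site, roster, emitted, subtype = site, site = site,
                    metadata = list(truth_records = qual,
                                    n_noise = nNoise))
    })
    names(cohorts) <- truth@sites
    cohorts
  })
}

#' Thin a cohort's calls into synthetic per-caller call sets
#'
#' Caller k's call set is the base cohort's qualifying records thinned
#' independently: each record is missed with probability
#' \code{dropRate[k]}.
#'
#' @param baseCohort a \linkS4class{CohortProfile} (filtered records).
#' @param nCallers number of callers (>= 2).
#' @param dropRate per-caller miss probability in [0, 1], recycled to
#'   \code{nCallers}.
#' @param seed integer seed.
#' @return list of \linkS4class{CallerCallSet}s named caller1..callerK.
#' @export
simCallerCalls <- function(baseCohort, nCallers, dropRate, seed = 1L) {
  if (nCallers < 2L) stop("need at least two callers")
  dropRate <- rep_len(dropRate, nCallers)
  if (any(dropRate < 0) || any(dropRate > 1))
    stop("dropRate must lie in [0, 1]")
  rec <- mutationRecords(baseCohort)
  withSeed(seed, {
    lapply(seq_len(nCallers), function(k) {
      keep <- stats::runif(nrow(rec)) >= dropRate[k]
      CallerCallSet(paste0("caller", k), rec[keep, , drop = FALSE])
    })
  })
}

#' Write a truth model to disk (YAML scalars + TSV matrices)
#'
#' @param truth a \linkS4class{MutationTruth}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(list(seed = truth@seed, noise = truth@noise,
                        alias_rate = truth@aliasRate,
                        lambda_extra = truth@lambdaExtra),
                   file.path(dir, "truth.yaml"))
  utils::write.table(data.frame(gene = truth@genes, truth@prob,
                                check.names = FALSE),
                     file.path(dir, "truth_prob.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(site = names(truth@incidence),
                                cases = unname(truth@incidence)),
                     file.path(dir, "truth_incidence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
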