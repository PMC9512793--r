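#' @include accessors.R
NULL

#' Rank genes and keep the top k
#'
#' @param rates named numeric of per-gene mutation rates.
#' @param k list length (default 50). If fewer than k genes have a nonzero
#'   rate, the list is truncated with a warning.
#' @param dropZero drop zero-rate genes before ranking (default TRUE).
#' @return data.frame (gene, rate) with rates nonincreasing; ties broken
#'   alphabetically by symbol, recorded in attribute \code{tie_rule}.
#' @export
rankTopK <- function(rates, k = 50L, dropZero = TRUE) {
  stopifnot(k >= 1L)
  if (anyDuplicated(names(rates))) stop("gene names must be unique")
  if (dropZero) rates <- rates[rates > 0]
  ord <- order(-rates, names(rates))
  if (length(ord) < k)
    warning("only ", length(ord), " genes with nonzero rate; list shorter than k = ", k)
  top <- utils::head(ord, k)
  out <- data.frame(gene = names(rates)[top], rate = unname(rates[top]))
  attr(out, "tie_rule") <- "alphabetical"
  out
}

#' Common rate of two top-k gene lists
#'
#' With T the combined list length and U the number of unique genes across
#' both lists, the common rate is 2 (T - U) / T. For two equal-size
#' deduplicated lists this equals the intersection fraction |A n B| / k.
#'
#' @param listA,listB character vectors of gene symbols, or data.frames
#'   from \code{\link{rankTopK}} (their \code{gene} column is used).
#' @return fraction in [0, 1].
#' @export
overlapRate <- function(listA, listB) {
  a <- unique(if (is.data.frame(listA)) listA$gene else listA)
  b <- unique(if (is.data.frame(listB)) listB$gene else listB)
  total <- length(a) + length(b)
  if (total == 0L) stop("both gene lists are empty")
  uniq <- length(union(a, b))
  2 * (total - uniq) / total
}

#' Classify a cancer's mutation pattern by TP53's rank
#'
#' The top-rate cluster is the set of genes whose rate is within
#' \code{delta} of the highest rate. If the cluster is TP53 alone the
#' cancer is "TP53-Top"; if TP53 sits in a cluster of two or three genes it
#' is "TP53-Plus"; otherwise "Non-TP53".
#'
#' @param ranked data.frame (gene, rate) from \code{\link{rankTopK}} or a
#'   named numeric of rates.
#' @param delta rate gap defining the top cluster (default 0.10, i.e. 10
#'   percentage points); reported alongside the label.
#' @param gene the anchor gene (default "TP53").
#' @return list with \code{label} (one of "TP53-Top", "TP53-Plus",
#'   "Non-TP53"), \code{cluster} (genes in the top cluster) and
#'   \code{delta}.
#' @export
classifyTp53Pattern <- function(ranked, delta = 0.10, gene = "TP53") {
  if (is.data.frame(ranked))
    rates <- stats::setNames(ranked$rate, ranked$gene)
  else rates <- ranked
  if (length(rates) == 0L) stop("empty ranked list")
  r1 <- max(rates)
  cluster <- sort(names(rates)[rates >= r1 - delta])
  label <- if (identical(cluster, gene)) paste0(gene, "-Top")
    else if (gene %in% cluster && length(cluster) %in% c(2L, 3L))
      paste0(gene, "-Plus")
    else paste0("Non-", gene)
  list(label = label, cluster = cluster, delta = delta)
}

#' Pearson correlation between two aligned rate vectors
#'
#' Vectors are aligned by gene name over the union of genes (a gene absent
#' from one side was unobserved there, so it contributes 0 rather than
#' being treated as missing); optionally a gene set is excluded first, as
#' when removing the dominant TP53 contribution.
#'
#' @param ratesA,ratesB named numerics of per-gene rates.
#' @param exclude optional character vector of genes to drop before the
#'   correlation.
#' @return list with \code{r}, \code{p}, \code{conf_int} and \code{n} from
#'   \code{stats::cor.test}.
#' @export
rateCorrelation <- function(ratesA, ratesB, exclude = NULL) {
  genes <- setdiff(union(names(ratesA), names(ratesB)), exclude)
  a <- stats::setNames(numeric(length(genes)), genes)
  b <- a
  a[intersect(genes, names(ratesA))] <- ratesA[intersect(genes, names(ratesA))]
  b[intersect(genes, names(ratesB))] <- ratesB[intersect(genes, names(ratesB))]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: a rate vector is constant")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       conf_int = as.numeric(ct$conf.int), n = length(genes))
}

#' Variance-gated two-sample comparison of rate vectors
#'
#' An F test compares the two variances first; when its p-value falls below
#' \code{fAlpha} the groups are compared with Welch's unequal-variance t
#' test, otherwise with the classic pooled-variance unpaired t test. All
#' components (F block, chosen branch, t, df, p, group means with standard
#' errors, confidence interval of the difference) are returned.
#'
#' @param ratesA,ratesB numeric vectors (named or not); compared as two
#'   independent groups.
#' @param fAlpha significance gate for the variance test (default 0.05).
#' @return list with elements \code{F}, \code{F_p}, \code{dfn}, \code{dfd},
#'   \code{test} ("pooled-t" or "welch-t"), \code{t}, \code{df}, \code{p},
#'   \code{meanA}, \code{seA}, \code{meanB}, \code{seB}, \code{conf_int}.
#' @export
compareRates <- function(ratesA, ratesB, fAlpha = 0.05) {
  a <- as.numeric(ratesA); b <- as.numeric(ratesB)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  ft <- stats::var.test(a, b)
  welch <- ft$p.value < fAlpha
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(F = unname(ft$statistic), F_p = ft$p.value,
       dfn = unname(ft$parameter[1L]), dfd = unname(ft$parameter[2L]),
       test = if (welch) "welch-t" else "pooled-t",
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       meanA = mean(a), seA = stats::sd(a) / sqrt(length(a)),
       meanB = mean(b), seB = stats::sd(b) / sqrt(length(b)),
       conf_int = as.numeric(tt$conf.int))
}
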