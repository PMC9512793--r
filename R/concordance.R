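#' @include accessors.R
NULL

#' Build a caller call set from mutation records
#'
#' @param callerId caller label.
#' @param x filtered record data.frame or \linkS4class{CohortProfile};
#'   records are grouped by gene into deduplicated patient sets.
#' @return a \linkS4class{CallerCallSet}.
#' @export
CallerCallSet <- function(callerId, x) {
  rec <- if (is(x, "CohortProfile")) mutationRecords(x) else x
  calls <- lapply(split(rec$sample_id, rec$gene), function(s)
    sort(unique(s)))
  new("CallerCallSet", callerId = as.character(callerId),
      calls = calls[order(names(calls))])
}

.geneLists <- function(callsets) lapply(callsets, function(cs)
  names(geneCalls(cs)))

#' Multiway shared-gene rate across callers
#'
#' The fraction of the union of per-caller mutated-gene lists that every
#' caller reports: |intersection| / |union|.
#'
#' @param callsets list of at least two \linkS4class{CallerCallSet}s.
#' @return list with \code{shared_genes}, \code{union_genes}, \code{rate}.
#' @export
multiwaySharedRate <- function(callsets) {
  if (length(callsets) < 2L) stop("need at least two call sets")
  gl <- .geneLists(callsets)
  uni <- Reduce(union, gl)
  if (length(uni) == 0L) stop("empty gene universe across callers")
  shared <- Reduce(intersect, gl)
  list(shared_genes = length(shared), union_genes = length(uni),
       rate = length(shared) / length(uni))
}

#' Pairwise shared-gene rate matrix
#'
#' @param callsets list of \linkS4class{CallerCallSet}s.
#' @return symmetric matrix of pairwise |intersection|/|union| rates with
#'   unit diagonal, dimnames = caller ids.
#' @export
pairwiseSharedRates <- function(callsets) {
  if (length(callsets) < 2L) stop("need at least two call sets")
  gl <- .geneLists(callsets)
  ids <- vapply(callsets, callerId, character(1))
  k <- length(gl)
  m <- diag(1, k)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    uni <- union(gl[[i]], gl[[j]])
    if (length(uni) == 0L) stop("empty gene universe for pair ",
                                ids[i], "/", ids[j])
    m[i, j] <- m[j, i] <- length(intersect(gl[[i]], gl[[j]])) / length(uni)
  }
  m
}

#' Per-gene patient-count table across callers
#'
#' @param callsets list of \linkS4class{CallerCallSet}s.
#' @return matrix genes x callers of deduplicated patient counts over the
#'   union gene universe, sorted by per-gene maximum count (descending).
#' @export
perGeneCountTable <- function(callsets) {
  gl <- .geneLists(callsets)
  genes <- sort(Reduce(union, gl))
  ids <- vapply(callsets, callerId, character(1))
  tab <- vapply(callsets, function(cs) {
    n <- vapply(geneCalls(cs), length, integer(1))
    out <- stats::setNames(integer(length(genes)), genes)
    out[intersect(names(n), genes)] <- n[intersect(names(n), genes)]
    out
  }, integer(length(genes)))
  tab <- matrix(tab, nrow = length(genes), ncol = length(ids),
                dimnames = list(genes, ids))
  if (nrow(tab))
    tab <- tab[order(-apply(tab, 1L, max), rownames(tab)), , drop = FALSE]
  tab
}

#' Summed absolute pairwise-difference error rate
#'
#' For every gene in the union universe, patient counts are compared
#' between all caller pairs; the metric is the sum of absolute pairwise
#' differences, normalised by (number of pairs) x (sum over genes of the
#' per-gene maximum count), giving a scale-free fraction that is 0 exactly
#' when all callers agree on every per-gene patient count.
#'
#' @param callsets list of \linkS4class{CallerCallSet}s.
#' @return fraction in [0, 1].
#' @export
maxErrorRate <- function(callsets) {
  tab <- perGeneCountTable(callsets)
  if (nrow(tab) == 0L || sum(tab) == 0L)
    stop("all-zero patient counts: error rate undefined")
  k <- ncol(tab)
  pairs <- utils::combn(k, 2L)
  sumdiff <- sum(apply(pairs, 2L, function(p)
    sum(abs(tab[, p[1L]] - tab[, p[2L]]))))
  denom <- ncol(pairs) * sum(apply(tab, 1L, max))
  sumdiff / denom
}
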