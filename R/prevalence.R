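#' @include accessors.R
NULL

#' Build the gene-by-site conditional mutation probability matrix
#'
#' Rows cover the full census panel (genes never observed get a zero row);
#' columns are the per-site cohorts in sorted site order. Entry (i, j) is
#' the fraction of site j's samples carrying at least one qualifying
#' mutation in gene i.
#'
#' @param tables list of per-site \linkS4class{GeneSampleTable}s, named by
#'   site code (or named after the tabulated cohorts' ids).
#' @param panel a \linkS4class{GenePanel}; defines the row universe.
#' @return a \linkS4class{ConditionalMatrix}.
#' @export
conditionalMatrix <- function(tables, panel) {
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(tables, cohortId, character(1))
  tables <- tables[order(names(tables))]
  genes <- sort(panelGenes(panel))
  N <- vapply(tables, nSamples, integer(1))
  if (any(N < 1L)) stop("site with N = 0 must be excluded upstream")
  cnt <- vapply(tables, function(tb) {
    m <- mutationCounts(tb)
    out <- stats::setNames(integer(length(genes)), genes)
    common <- intersect(names(m), genes)
    out[common] <- m[common]
    out
  }, integer(length(genes)))
  cnt <- matrix(cnt, nrow = length(genes),
                dimnames = list(genes, names(tables)))
  prob <- sweep(cnt, 2L, N, `/`)
  new("ConditionalMatrix", SummarizedExperiment::SummarizedExperiment(
    assays = list(count = cnt, prob = prob),
    colData = S4Vectors::DataFrame(N = N, row.names = names(tables))))
}

#' @describeIn conditionalMatrix conditional probability assay
#' @param x a ConditionalMatrix
#' @export
condProb <- function(x) SummarizedExperiment::assay(x, "prob")

#' @describeIn conditionalMatrix mutated-sample count assay
#' @export
mutCounts <- function(x) SummarizedExperiment::assay(x, "count")

#' @describeIn conditionalMatrix per-site cohort sizes
#' @export
cohortSizes <- function(x) stats::setNames(x$N, colnames(x))

.alignWeights <- function(mat, v) {
  w <- if (is(v, "WeightVector")) siteWeights(v) else v
  if (!setequal(names(w), colnames(mat))) {
    miss <- setdiff(colnames(mat), names(w))
    extra <- setdiff(names(w), colnames(mat))
    stop("site mismatch between matrix and weights",
         if (length(miss)) paste0("; matrix-only: ",
                                  paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; weights-only: ",
                                   paste(extra, collapse = ", ")))
  }
  w[colnames(mat)]
}

#' Epidemiologically weighted mutation proportions
#'
#' The population-level mutation proportion of each gene is the scalar
#' product of its per-site conditional probabilities with the site weight
#' vector: P_i = sum_j prob[i, j] * v_j.
#'
#' @param mat a \linkS4class{ConditionalMatrix}.
#' @param v a \linkS4class{WeightVector} (or named numeric) over exactly
#'   the matrix's sites.
#' @return named numeric of per-gene weighted proportions in [0, 1].
#' @export
weightedProportions <- function(mat, v) {
  w <- .alignWeights(mat, v)
  drop(condProb(mat) %*% w)
}

#' Poisson parametric-bootstrap confidence intervals
#'
#' For each replicate, every mutated-sample count is re-drawn from a
#' Poisson distribution whose mean is the observed count (draws are clamped
#' at the cohort size so probabilities stay in [0, 1]), the weighted
#' proportion is recomputed through the same scalar product, and the 95%
#' interval is the empirical 2.5/97.5 percentile over replicates. One RNG
#' stream, seeded once, replicate-major: results are reproducible.
#'
#' @param mat a \linkS4class{ConditionalMatrix}.
#' @param v weight vector over the matrix's sites.
#' @param nReps number of in-silico datasets (default 2000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return data.frame (gene, estimate, sim_mean, ci_low, ci_high) sorted by
#'   decreasing estimate; attributes \code{n_replicates} and \code{seed}.
#' @export
poissonCI <- function(mat, v, nReps = 2000L, seed = 1L, level = 0.95) {
  if (nReps < 2L) stop("nReps must be >= 2")
  w <- .alignWeights(mat, v)
  cnt <- mutCounts(mat)
  N <- cohortSizes(mat)
  point <- drop(sweep(cnt, 2L, N, `/`) %*% w)
  m <- nrow(cnt); n <- ncol(cnt); ncell <- m * n
  sims <- withSeed(seed, {
    ## replicate-major: each replicate draws the full cell grid in
    ## column-major (gene within site) order from one RNG stream
    draws <- matrix(stats::rpois(ncell * nReps, rep(as.vector(cnt), nReps)),
                    nrow = ncell)
    draws <- pmin(draws, rep(N, each = m))        # clamp count* <= N[j]
    wn <- rep(w / N, each = m)                    # cell weight v_j / N_j
    ## sum the weighted cells over sites for each gene and replicate
    colSums(aperm(array(draws * wn, c(m, n, nReps)), c(2L, 1L, 3L)))
  })
  if (is.null(dim(sims))) sims <- matrix(sims, nrow = m)
  qs <- apply(sims, 1L, stats::quantile,
              probs = c((1 - level) / 2, 1 - (1 - level) / 2),
              names = FALSE)
  out <- data.frame(gene = rownames(cnt), estimate = unname(point),
                    sim_mean = unname(rowMeans(sims)),
                    ci_low = qs[1L, ], ci_high = qs[2L, ])
  out <- out[order(-out$estimate, out$gene), ]
  rownames(out) <- NULL
  attr(out, "n_replicates") <- nReps
  attr(out, "seed") <- seed
  out
}

#' Accumulated mutation rate of a gene in a cohort
#'
#' Total qualifying mutation events divided by patient count; unlike the
#' prevalence (at most one count per sample) this can exceed 1 when samples
#' carry several mutations in the gene.
#'
#' @param table a \linkS4class{GeneSampleTable}.
#' @param gene gene symbol.
#' @return nonnegative fraction (may exceed 1).
#' @export
accumulatedRate <- function(table, gene) {
  if (nSamples(table) == 0L) stop("empty cohort")
  rc <- recordCounts(table)
  n <- if (gene %in% names(rc)) rc[[gene]] else 0L
  n / nSamples(table)
}

#' Per-gene mutation proportions of one cohort
#'
#' @param table a \linkS4class{GeneSampleTable}.
#' @param genes optional gene universe; genes without records get 0.
#' @return named numeric of |mutated samples| / N.
#' @export
mutationRates <- function(table, genes = NULL) {
  m <- mutationCounts(table) / nSamples(table)
  if (is.null(genes)) return(m)
  out <- stats::setNames(numeric(length(genes)), genes)
  common <- intersect(names(m), genes)
  out[common] <- m[common]
  out
}
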