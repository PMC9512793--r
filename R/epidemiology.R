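#' @include accessors.R
NULL

#' Merge subtype cohorts into major-site cohorts
#'
#' Subtype profiles (e.g. 94 detailed subtypes) are concatenated into one
#' cohort per ICD-10-style major site. Sample rosters and record tables are
#' simply unioned; total sample count is conserved.
#'
#' @param profiles list of \linkS4class{CohortProfile}s.
#' @param map named character vector subtype -> site (see
#'   \code{\link{readSiteMap}}); must cover every subtype present.
#' @return list of per-site \linkS4class{CohortProfile}s, named by site.
#' @export
aggregateProfiles <- function(profiles, map) {
  subtypes <- vapply(profiles, function(p) p@subtype, character(1))
  unmapped <- setdiff(subtypes, names(map))
  if (length(unmapped))
    stop("subtype codes missing from the site map: ",
         paste(unique(unmapped), collapse = ", "))
  sites <- unname(map[subtypes])
  out <- lapply(split(profiles, sites), function(group) {
    roster <- do.call(rbind, lapply(group, sampleRoster))
    rec <- do.call(rbind, lapply(group, mutationRecords))
    dup <- unique(roster$sample_id[duplicated(roster$sample_id)])
    if (length(dup))
      stop("sample ids shared across merged cohorts: ",
           paste(utils::head(dup, 5L), collapse = ", "))
    site <- unname(map[group[[1L]]@subtype])
    CohortProfile(site, roster, rec, subtype = site, site = site)
  })
  out[order(names(out))]
}

#' Preliminary incidence weights over all registry sites
#'
#' Incidence is summed over all available years within each site and
#' divided by the grand total, yielding each site's fraction of all cancer
#' cases. (Summing and year-averaging give identical weights since the
#' divisor cancels.)
#'
#' @param incidence data.frame with columns \code{site}, \code{year},
#'   \code{cases} (see \code{\link{readIncidence}}), or a named numeric of
#'   per-site case counts.
#' @return a \linkS4class{WeightVector} with \code{Q = 0} and
#'   \code{rescaled = FALSE}; weights cover all sites in the table.
#' @export
preliminaryWeights <- function(incidence) {
  if (is.data.frame(incidence)) {
    tot <- tapply(incidence$cases, incidence$site, sum)
    cases <- stats::setNames(as.numeric(tot), names(tot))
  } else {
    cases <- incidence
  }
  if (any(cases < 0)) stop("incidence cases must be nonnegative")
  if (sum(cases) <= 0) stop("incidence table has no cases")
  w <- cases / sum(cases)
  w <- w[order(names(w))]
  new("WeightVector", weights = w, preliminary = w, Q = 0,
      rescaled = FALSE)
}

#' Rescale weights to the sites with sequencing data
#'
#' The incidence mass of sites lacking sequencing data is the coverage gap
#' Q; weights of sequenced sites are divided by (1 - Q) so the final vector
#' sums to 1 over exactly the sites entering the conditional matrix.
#' Sequenced sites absent from the incidence table get weight 0 with a
#' warning (the analysis intersects the two datasets).
#'
#' @param prelim a \linkS4class{WeightVector} of preliminary weights.
#' @param sequencedSites character vector of site codes with cohorts.
#' @return a rescaled \linkS4class{WeightVector} over
#'   \code{sequencedSites}.
#' @export
rescaleForCoverage <- function(prelim, sequencedSites) {
  if (length(sequencedSites) == 0L) stop("no sequenced sites")
  p <- preliminaryWeightsOf(prelim)
  extra <- setdiff(sequencedSites, names(p))
  if (length(extra)) {
    warning("sequenced sites absent from incidence get weight 0: ",
            paste(extra, collapse = ", "))
    p[extra] <- 0
  }
  Q <- sum(p[setdiff(names(p), sequencedSites)])
  if (1 - Q <= 0)
    stop("no incidence mass on sequenced sites (Q = 1)")
  w <- p[sequencedSites] / (1 - Q)
  w <- w[order(names(w))]
  new("WeightVector", weights = w, preliminary = p[order(names(p))],
      Q = unname(Q), rescaled = TRUE)
}

#' Convert an ICD-O-3-based weight vector onto ICD-10 sites
#'
#' Weights keyed by ICD-O-3 categories are re-allocated onto ICD-10 major
#' sites by summing the mapped categories (mass is conserved), after which
#' coverage rescaling restricts to the sequenced sites.
#'
#' @param weights named numeric of ICD-O-3 category weights, or a
#'   \linkS4class{WeightVector} (its preliminary weights are used).
#' @param map named character vector ICD-O-3 category -> ICD-10 site; must
#'   cover every category present.
#' @param sequencedSites ICD-10 sites with sequencing data; default all
#'   mapped sites (no rescaling beyond renormalisation).
#' @return a \linkS4class{WeightVector} on ICD-10 sites.
#' @export
convertIcdo3 <- function(weights, map, sequencedSites = NULL) {
  w <- if (is(weights, "WeightVector")) preliminaryWeightsOf(weights)
       else weights
  unmapped <- setdiff(names(w), names(map))
  if (length(unmapped))
    stop("ICD-O-3 categories missing from the map: ",
         paste(unmapped, collapse = ", "))
  agg <- tapply(w, unname(map[names(w)]), sum)
  agg <- stats::setNames(as.numeric(agg), names(agg))
  agg <- agg / sum(agg)   # guard against input not summing exactly to 1
  prelim <- new("WeightVector", weights = agg[order(names(agg))],
                preliminary = agg[order(names(agg))], Q = 0,
                rescaled = FALSE)
  if (is.null(sequencedSites)) sequencedSites <- names(agg)
  rescaleForCoverage(prelim, sequencedSites)
}
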