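# Assemble a ConditionalMatrix from explicit counts for forced-arithmetic
# cases.
mkMatrix <- function(counts, N) {
  tables <- lapply(seq_len(ncol(counts)), function(j) {
    mut <- lapply(rownames(counts), function(g)
      if (counts[g, j] > 0) paste0("S", seq_len(counts[g, j])) else character())
    names(mut) <- rownames(counts)
    mut <- mut[counts[, j] > 0]
    new("GeneSampleTable", cohortId = colnames(counts)[j],
        N = as.integer(N[j]), mutated = mut,
        recordCounts = vapply(mut, length, integer(1)))
  })
  names(tables) <- colnames(counts)
  conditionalMatrix(tables, GenePanel(rownames(counts)))
}

test_that("conditional matrix holds count/N with zero rows for unseen genes", {
  cnt <- matrix(c(2L, 0L), nrow = 2,
                dimnames = list(c("TP53", "GHOST"), "C01"))
  m <- mkMatrix(cnt, N = 4)
  expect_equal(condProb(m)["TP53", "C01"], 0.5)
  expect_equal(condProb(m)["GHOST", "C01"], 0)
  expect_equal(cohortSizes(m), c(C01 = 4L))
})

test_that("conditional matrix equals a brute-force per-sample recount", {
  truth <- simTruth(8, 3, seed = 17, noise = 0.1)
  panel <- truthPanel(truth)
  cohorts <- lapply(simCohorts(truth, 50, seed = 17), function(co)
    filterRecords(resolveSynonyms(co, panel), panel))
  m <- conditionalMatrix(lapply(cohorts, tabulateCohort), panel)
  for (site in names(cohorts)) {
    oracle <- bruteTabulate(dedupRecords(mutationRecords(cohorts[[site]])))
    for (g in rownames(m)) {
      expected <- if (g %in% names(oracle)) length(oracle[[g]]) else 0L
      expect_identical(unname(mutCounts(m)[g, site]), expected)
    }
  }
  expect_error(
    conditionalMatrix(list(new("GeneSampleTable", cohortId = "x", N = 1L,
                               mutated = list(), recordCounts = integer())[
                                 integer(0)]), panel))
})

test_that("weighted proportions are the scalar product with v", {
  cnt <- matrix(c(5L, 2L), nrow = 1, dimnames = list("TP53", c("A", "B")))
  m <- mkMatrix(cnt, N = c(10, 10))
  expect_equal(unname(weightedProportions(m, c(A = 0.6, B = 0.4))), 0.38)
  # single site, v = 1: proportion passes through
  m1 <- mkMatrix(matrix(3L, 1, 1, dimnames = list("TP53", "A")), N = 6)
  expect_equal(unname(weightedProportions(m1, c(A = 1))), 0.5)
  expect_error(weightedProportions(m, c(A = 0.5, C = 0.5)), "mismatch")
})

test_that("weighted proportions equal a pseudo-population patient count", {
  # constant N per site so integer incidence counts give an exact
  # individual-level replication oracle
  set.seed(123)
  for (rep in 1:5) {
    nG <- sample(3:20, 1); nS <- sample(2:6, 1); N <- 200
    truth <- simTruth(nG, nS, seed = rep, noise = 0)
    cohorts <- simCohorts(truth, N, seed = rep + 100)
    panel <- truthPanel(truth)
    tables <- lapply(cohorts, function(co)
      tabulateCohort(filterRecords(resolveSynonyms(co, panel), panel)))
    m <- conditionalMatrix(tables, panel)
    cases <- sample(1:30, nS)
    v <- stats::setNames(cases / sum(cases), names(cohorts))
    got <- weightedProportions(m, v)
    # pseudo-population: replicate each site's per-sample indicators
    # cases[j] times and count the mutated fraction directly
    for (g in sample(rownames(m), min(5, nG))) {
      indicators <- unlist(lapply(seq_along(tables), function(j) {
        mut <- sampleRoster(cohorts[[j]])$sample_id %in%
          mutatedSamples(tables[[j]], g)
        rep(mut, cases[j])
      }))
      expect_equal(unname(got[g]), mean(indicators), tolerance = 1e-12)
    }
  }
})

test_that("weighted proportions are permutation-invariant and monotone", {
  cnt <- matrix(c(5L, 2L, 1L, 7L), nrow = 2,
                dimnames = list(c("TP53", "KRAS"), c("A", "B")))
  m <- mkMatrix(cnt, N = c(10, 20))
  v <- c(A = 0.3, B = 0.7)
  expect_equal(weightedProportions(m, v), weightedProportions(m, rev(v)))
  # raising one entry's count cannot lower the estimate
  cnt2 <- cnt; cnt2["KRAS", "B"] <- 9L
  m2 <- mkMatrix(cnt2, N = c(10, 20))
  expect_gt(weightedProportions(m2, v)[["KRAS"]],
            weightedProportions(m, v)[["KRAS"]])
})

test_that("Poisson bootstrap handles the degenerate corners", {
  zero <- mkMatrix(matrix(0L, 2, 1, dimnames = list(c("A1", "B1"), "S")),
                   N = 5)
  ci <- poissonCI(zero, c(S = 1), nReps = 50, seed = 1)
  expect_true(all(ci$ci_low == 0 & ci$ci_high == 0 & ci$estimate == 0))

  full <- mkMatrix(matrix(4L, 1, 1, dimnames = list("A1", "S")), N = 4)
  ci2 <- poissonCI(full, c(S = 1), nReps = 200, seed = 1)
  expect_equal(ci2$ci_high, 1)       # clamped at N
  expect_true(all(ci2$ci_low >= 0 & ci2$ci_high <= 1))
  expect_error(poissonCI(full, c(S = 1), nReps = 1), ">= 2")
})

test_that("Poisson bootstrap is bit-identical under a fixed seed", {
  truth <- simTruth(10, 3, seed = 3)
  panel <- truthPanel(truth)
  tables <- lapply(simCohorts(truth, 60, seed = 3), function(co)
    tabulateCohort(filterRecords(resolveSynonyms(co, panel), panel)))
  m <- conditionalMatrix(tables, panel)
  v <- rescaleForCoverage(preliminaryWeights(truthIncidence(truth)),
                          truth@sites)
  a <- poissonCI(m, v, nReps = 2000, seed = 99)
  b <- poissonCI(m, v, nReps = 2000, seed = 99)
  expect_identical(a, b)
  c <- poissonCI(m, v, nReps = 2000, seed = 100)
  expect_false(identical(a$ci_low, c$ci_low))
})

test_that("CI width shrinks as counts grow at fixed proportions", {
  widths <- vapply(c(20, 200, 2000), function(N) {
    m <- mkMatrix(matrix(as.integer(0.2 * N), 1, 1,
                         dimnames = list("TP53", "S")), N = N)
    ci <- poissonCI(m, c(S = 1), nReps = 1000, seed = 5)
    ci$ci_high - ci$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("accumulated rate uses raw record totals and can exceed 1", {
  rec <- mkRecords(c("S1", "S1"), c("EGFR", "EGFR"), rep("missense", 2),
                   pos = c(1, 2))
  tb <- tabulateCohort(mkCohort("c", "S1", rec))
  expect_equal(accumulatedRate(tb, "EGFR"), 2.0)
  expect_gte(accumulatedRate(tb, "EGFR"),
             mutationRates(tb)[["EGFR"]])

  one <- tabulateCohort(mkCohort("c", c("S1", "S2"),
                                 mkRecords(c("S1", "S2"), c("EGFR", "EGFR"),
                                           rep("missense", 2))))
  expect_equal(accumulatedRate(one, "EGFR"),
               mutationRates(one)[["EGFR"]])
  expect_equal(accumulatedRate(one, "ABSENT"), 0)
})

test_that("pipeline estimates recover the true weighted proportions", {
  truth <- simTruth(15, 4, seed = 41, noise = 0.05, aliasRate = 0.1)
  N <- 2000
  cohorts <- simCohorts(truth, N, seed = 41)
  panel <- truthPanel(truth)
  tables <- lapply(cohorts, function(co)
    tabulateCohort(filterRecords(resolveSynonyms(co, panel), panel)))
  m <- conditionalMatrix(tables, panel)
  v <- rescaleForCoverage(preliminaryWeights(truthIncidence(truth)),
                          truth@sites)
  est <- weightedProportions(m, v)
  tru <- trueWeighted(truth, v)
  w <- siteWeights(v)
  sds <- sqrt(drop((trueProb(truth)[, names(w)] *
                      (1 - trueProb(truth)[, names(w)]) / N) %*% w^2))
  ok <- abs(est[names(tru)] - tru) <= 3 * sds + 1e-12
  expect_gte(mean(ok), 0.95)
})
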