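test_that("top-k ranking sorts by rate with alphabetical tie-break", {
  rates <- c(APC = 0.1, TP53 = 0.5, KRAS = 0.3)
  top2 <- rankTopK(rates, k = 2)
  expect_identical(top2$gene, c("TP53", "KRAS"))
  expect_true(all(diff(top2$rate) <= 0))

  ties <- rankTopK(c(B = 0.2, A = 0.2, C = 0.2), k = 3)
  expect_identical(ties$gene, c("A", "B", "C"))
  expect_identical(attr(ties, "tie_rule"), "alphabetical")

  expect_warning(rankTopK(c(A = 0.5, B = 0), k = 3), "shorter")

  set.seed(8)
  r <- stats::setNames(runif(40), paste0("g", sprintf("%02d", 1:40)))
  top <- rankTopK(r, k = 10)
  oracle <- names(sort(r, decreasing = TRUE))[1:10]
  expect_identical(top$gene, oracle)
})

test_that("common rate 2(T-U)/T matches the intersection fraction", {
  a <- paste0("g", 1:50)
  b <- c(paste0("g", 1:40), paste0("h", 1:10))
  expect_equal(overlapRate(a, b), 0.80)
  expect_equal(overlapRate(a, a), 1.0)
  expect_equal(overlapRate(a, paste0("x", 1:50)), 0.0)
  expect_error(overlapRate(character(), character()), "empty")
  # symmetry
  expect_equal(overlapRate(a, b), overlapRate(b, a))
})

test_that("overlap identity holds exhaustively for small equal-size lists", {
  universe <- paste0("g", 1:10)
  for (k in 1:6) {
    combs <- utils::combn(universe, k, simplify = FALSE)
    n <- length(combs)
    got <- numeric(n * n); want <- numeric(n * n)
    idx <- 0L
    for (a in combs) for (b in combs) {
      idx <- idx + 1L
      got[idx] <- overlapRate(a, b)
      want[idx] <- length(intersect(a, b)) / k
    }
    expect_equal(got, want)
  }
})

test_that("TP53 pattern rule reproduces the three archetypes", {
  top <- classifyTp53Pattern(c(TP53 = 0.935, GEN1 = 0.30, GEN2 = 0.2))
  expect_identical(top$label, "TP53-Top")
  expect_identical(top$cluster, "TP53")

  plus <- classifyTp53Pattern(c(EGFR = 0.587, TP53 = 0.55, KRAS = 0.20))
  expect_identical(plus$label, "TP53-Plus")
  expect_identical(plus$cluster, c("EGFR", "TP53"))

  non <- classifyTp53Pattern(c(BRAF = 0.60, NRAS = 0.20, TP53 = 0.10))
  expect_identical(non$label, "Non-TP53")

  # invariant to genes far below the cluster threshold
  withTail <- classifyTp53Pattern(c(TP53 = 0.935, GEN1 = 0.30, GEN2 = 0.2,
                                    Z1 = 0.01, Z2 = 0.005))
  expect_identical(withTail$label, top$label)
  expect_identical(withTail$cluster, top$cluster)

  # four-gene cluster containing TP53 is not "Plus"
  four <- classifyTp53Pattern(c(TP53 = 0.5, A = 0.48, B = 0.46, C = 0.44))
  expect_identical(four$label, "Non-TP53")
})

test_that("rate correlation aligns by gene, imputes zeros, honours exclude", {
  a <- c(TP53 = 0.5, KRAS = 0.3, APC = 0.1)
  expect_equal(rateCorrelation(a, a)$r, 1.0)
  expect_error(rateCorrelation(a, c(TP53 = 0.2, KRAS = 0.2, APC = 0.2)),
               "constant")

  # gene absent from one side counts as unobserved (rate 0)
  b <- c(TP53 = 0.4, KRAS = 0.25)
  manual <- stats::cor(c(0.5, 0.3, 0.1), c(0.4, 0.25, 0))
  expect_equal(rateCorrelation(a, b)$r, manual)

  # excluding the dominant gene changes the alignment
  set.seed(21)
  x <- stats::setNames(runif(30), paste0("g", 1:30))
  y <- x + rnorm(30, sd = 0.05)
  names(y) <- names(x)
  full <- rateCorrelation(x, y)
  reduced <- rateCorrelation(x, y, exclude = "g1")
  expect_identical(reduced$n, 29L)
  expect_false(identical(full$r, reduced$r))

  # affine invariance
  expect_equal(rateCorrelation(x, stats::setNames(3 * y + 2, names(y)))$r,
               full$r)
})

test_that("variance-gated comparison picks the branch the F test dictates", {
  set.seed(5)
  a <- rnorm(40, 0, 1)
  bSame <- a + 0.3                 # equal variance by construction (F = 1)
  res <- compareRates(a, bSame)
  expect_identical(res$test, "pooled-t")
  # pooled branch equals the classic equal-variance t test
  tt <- stats::t.test(a, bSame, var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic))
  expect_equal(res$df, unname(tt$parameter))
  expect_equal(res$p, tt$p.value)

  bWide <- rnorm(40, 0, 6)         # variance ratio far from 1
  res2 <- compareRates(a, bWide)
  expect_identical(res2$test, "welch-t")
  tw <- stats::t.test(a, bWide, var.equal = FALSE)
  expect_equal(res2$t, unname(tw$statistic))
  expect_equal(res2$df, unname(tw$parameter))

  same <- compareRates(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(compareRates(1, c(1, 2)), "at least 2")
})
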