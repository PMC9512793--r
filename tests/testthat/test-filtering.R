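test_that("tier-1 keeps exactly the panel-member records", {
  panel <- tinyPanel()
  rec <- mkRecords(paste0("S", 1:6),
                   c("TP53", "EGFR", "ZZZ1", "KRAS", "ZZZ2", "TP53"),
                   rep("missense", 6))
  out <- tier1Filter(rec, panel)
  expect_identical(out$gene, c("TP53", "EGFR", "KRAS", "TP53"))
  # brute-force membership scan as oracle
  expect_identical(out, rec[rec$gene %in% c("TP53", "EGFR", "KRAS"), ])

  expect_identical(tier1Filter(rec[rec$gene == "TP53", ], panel),
                   rec[rec$gene == "TP53", ])
  expect_identical(nrow(tier1Filter(rec[rec$gene == "ZZZ1", ], panel)), 0L)
  expect_error(tier1Filter(rec, GenePanel(character())), "at least one")
})

test_that("tier-2 retains exactly the protein-altering classes", {
  rec <- mkRecords(paste0("S", seq_along(VARIANT_CLASSES)),
                   rep("TP53", length(VARIANT_CLASSES)), VARIANT_CLASSES)
  out <- tier2Filter(rec)
  expect_setequal(out$variant_class,
                  c("missense", "nonsense", "frameshift", "inframe_indel",
                    "splice"))
  expect_false(any(c("silent", "noncoding", "SV", "fusion", "other") %in%
                     out$variant_class))
  # truncating-only configuration drops frameshifts
  noFs <- tier2Filter(rec, retain = setdiff(PROTEIN_ALTERING, "frameshift"))
  expect_false("frameshift" %in% noFs$variant_class)
})

test_that("the two tiers commute", {
  truth <- simTruth(12, 1, seed = 5, noise = 0.2)
  panel <- truthPanel(truth)
  rec <- resolveSynonyms(
    mutationRecords(simCohorts(truth, 80, seed = 5)[[1]]), panel)
  a <- tier2Filter(tier1Filter(rec, panel))
  b <- tier1Filter(tier2Filter(rec), panel)
  expect_identical(sortRecords(a), sortRecords(b))
})

test_that("filtering removes injected noise records and only them", {
  truth <- simTruth(15, 2, seed = 6, noise = 0.25, aliasRate = 0.3)
  panel <- truthPanel(truth)
  for (co in simCohorts(truth, 60, seed = 6)) {
    filtered <- filterRecords(resolveSynonyms(co, panel), panel)
    expect_identical(sortRecords(mutationRecords(filtered)),
                     sortRecords(co@metadata$truth_records))
  }
})

test_that("tabulation counts a gene at most once per sample", {
  rec <- mkRecords(c("S1", "S1", "S2"), c("EGFR", "EGFR", "EGFR"),
                   rep("missense", 3))
  co <- mkCohort("c", c("S1", "S2", "S3"), rec)
  tb <- tabulateCohort(co)
  expect_identical(mutationCounts(tb)[["EGFR"]], 2L)
  expect_identical(recordCounts(tb)[["EGFR"]], 3L)
  expect_identical(mutatedSamples(tb, "EGFR"), c("S1", "S2"))
  expect_error(tabulateCohort(mkCohort("empty", character())), "no samples")
})

test_that("identical duplicate calls are collapsed before tabulation", {
  dup <- mkRecords(c("S1", "S1"), c("TP53", "TP53"), c("missense", "missense"),
                   pos = c(100, 100))
  co <- mkCohort("c", "S1", dup)
  expect_identical(recordCounts(tabulateCohort(co))[["TP53"]], 1L)
  expect_identical(recordCounts(tabulateCohort(co, collapseDuplicates = FALSE))[["TP53"]],
                   2L)
})

test_that("tabulation matches a brute-force per-sample scan", {
  truth <- simTruth(10, 1, seed = 9, noise = 0)
  panel <- truthPanel(truth)
  co <- filterRecords(resolveSynonyms(simCohorts(truth, 70, seed = 9)[[1]],
                                      panel), panel)
  tb <- tabulateCohort(co)
  oracle <- bruteTabulate(dedupRecords(mutationRecords(co)))
  expect_identical(tb@mutated[sort(names(tb@mutated))], oracle)
  expect_true(all(mutationCounts(tb) <= nSamples(tb)))
  expect_true(all(mutationRates(tb) >= 0 & mutationRates(tb) <= 1))
})

test_that("stratification subsets roster and records correctly", {
  roster <- data.frame(sample_id = paste0("S", 1:6),
                       gender = c("female", "female", "male", "male",
                                  "female", "unknown"),
                       smoking = c("smoker", "non-smoker", "non-smoker",
                                   "unknown", "non-smoker", "smoker"))
  rec <- mkRecords(paste0("S", 1:6), rep("TP53", 6), rep("missense", 6))
  co <- mkCohort("c", roster, rec)

  fns <- stratifyCohort(co, gender = "female", smoking = "non-smoker")
  expect_setequal(sampleRoster(fns)$sample_id, c("S2", "S5"))
  expect_setequal(mutationRecords(fns)$sample_id, c("S2", "S5"))
  # unknowns excluded unless requested
  expect_false("S6" %in% sampleRoster(stratifyCohort(co, gender = "female"))$sample_id)
  expect_true("S6" %in%
    sampleRoster(stratifyCohort(co, gender = c("female", "unknown")))$sample_id)

  allF <- stratifyCohort(co, gender = "female")
  expect_identical(sortRecords(mutationRecords(stratifyCohort(allF, gender = "female"))),
                   sortRecords(mutationRecords(allF)))
  expect_warning(stratifyCohort(allF, gender = "male"), "empty")
})
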