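# oncoprev

Population-level prevalence of mutated cancer genes, estimated by combining
cohort sequencing profiles with cancer-registry incidence statistics.

## The problem

Sequencing cohorts tell you how often a gene is mutated *within a cancer
type*; registries tell you how common each cancer type is *within a
population*. Neither alone answers the question a screening programme or a
drug developer asks: *what fraction of all cancer patients in this
population carry a mutation in gene g?* oncoprev answers it by weighting
per-site conditional mutation probabilities with incidence-derived site
weights.

The estimator is, for gene *i*,

    P_i = sum_j  prob[i, j] * v_j

where `prob[i, j]` is the conditional probability that gene *i* is mutated
in cancer site *j* (the fraction of site *j*'s cohort with at least one
qualifying mutation in the gene — a sample counts at most once per gene),
and `v` is the site weight vector: each site's share of total registry
incidence, rescaled by `1 / (1 - Q)` where the coverage gap *Q* is the
incidence mass of sites that lack sequencing data. Uncertainty comes from a
Poisson parametric bootstrap: each mutated-sample count is re-drawn with its
observed value as the mean (clamped at the cohort size), the scalar product
is recomputed per replicate, and the 95% interval is the empirical
2.5/97.5 percentile over 2000 replicates.

Around that core the package provides:

* MAF-style I/O with configurable column/vocabulary dialects and gene
  synonym resolution;
* two-tier filtering — a cancer-gene census panel, then protein-altering
  consequences only (missense, nonsense, frameshift, inframe indel,
  splice);
* subtype-to-ICD-10-site aggregation and ICD-O-3 to ICD-10 re-weighting;
* cohort comparison: top-k ranking, the common rate `2(T - U)/T`, TP53
  pattern classification (TP53-Top / TP53-Plus / Non-TP53), aligned-vector
  Pearson correlation, and an F-test-gated pooled/Welch t comparison;
* variant-caller concordance: multiway and pairwise shared-gene rates and
  a summed absolute pairwise-difference error metric;
* a synthetic-cohort generator with known ground truth, so the whole
  pipeline is testable end to end without external data.

## Worked example

```r
library(oncoprev)

truth   <- simTruth(50, 6, seed = 42)        # 50 genes x 6 sites (+2 unsequenced)
cohorts <- simCohorts(truth, 400, seed = 43) # 400 samples per site
panel   <- truthPanel(truth)

tables <- lapply(cohorts, function(co)
  tabulateCohort(filterRecords(resolveSynonyms(co, panel), panel)))
mat <- conditionalMatrix(tables, panel)
w   <- rescaleForCoverage(preliminaryWeights(truthIncidence(truth)),
                          truth@sites)
w
#> WeightVector over 6 sequenced sites (Q = 0.2617, rescaled)

prev <- poissonCI(mat, w, nReps = 2000, seed = 44)
head(prev, 3)
#>     gene estimate sim_mean ci_low ci_high
#> 1   TP53    0.563    0.563  0.530   0.597
#> 2 GEN012    0.249    0.249  0.225   0.274
#> 3 GEN015    0.246    0.246  0.221   0.271
```

The dominant gene's weighted prevalence is 56.3% of the simulated patient
population (bootstrap 95% CI 53.0–59.7%); 26.2% of registry incidence fell
on sites without sequencing data and was rescaled away (`Q`). The estimated
top-20 list recovers the true top-20 exactly here
(`overlapRate(...) == 1`), and the first site classifies as TP53-Top:

```r
classifyTp53Pattern(mutationRates(tables[[1]], panelGenes(panel)))
#> $label   "TP53-Top"
#> $cluster "TP53"
#> $delta   0.1
```

File-based studies run the same stages through a YAML config and
`runPipeline()`, or the thin CLI at `inst/scripts/oncoprev`
(`simulate`, `prevalence`, `compare`, `concordance`, `convert-icd`).

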