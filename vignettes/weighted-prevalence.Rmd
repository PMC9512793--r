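---
title: "Incidence-weighted mutation prevalence: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incidence-weighted mutation prevalence: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoprev)
```

## The model

oncoprev estimates the fraction of a cancer patient population carrying a
mutation in each gene of a census panel. Two ingredients are combined:

1. **Conditional mutation probabilities.** For each gene $i$ and cancer
   site $j$, $p_{ij}$ is the fraction of site $j$'s sequenced cohort with
   at least one qualifying mutation in gene $i$. "Qualifying" means the
   record survived two filters: membership of the census panel (tier 1)
   and a protein-altering consequence class — missense, nonsense,
   frameshift, inframe indel, or splice (tier 2). A sample contributes at
   most one count per gene however many records it carries, so $p_{ij}$ is
   a per-patient probability, not a per-mutation rate.

2. **Incidence weights.** Each site's weight is its share of total
   registry incidence, summed over all available years. Sites present in
   the registry but absent from the sequencing data contribute their mass
   to the coverage gap $Q$; the weights of sequenced sites are divided by
   $1 - Q$ so they sum to one over exactly the sites in the matrix. When
   the registry is keyed in ICD-O-3 categories, the categories are first
   re-allocated onto ICD-10 major sites by summation (mass-conserving)
   and the same rescaling follows.

The population prevalence of gene $i$ is the scalar product
$P_i = \sum_j p_{ij} v_j$. The implicit assumptions are worth stating: the
sequenced cohort of each site is treated as representative of that site's
patient population; incidence shares are treated as the correct mixing
proportions (no age-standardisation — the package consumes registry
outputs, it does not recompute them); and genes are treated marginally
(no co-mutation structure enters the estimate).

Weights are computed from case *counts*. Crude rates would give identical
weights only under equal population denominators across sites; counts are
what "share of all cancer cases" means, so they are the default and the
only supported input.

## Uncertainty

Confidence intervals come from a Poisson parametric bootstrap
(`poissonCI()`). For each of `nReps = 2000` replicates, every
mutated-sample count $k_{ij}$ is re-drawn as
$k^*_{ij} \sim \mathrm{Poisson}(k_{ij})$, the full estimation pipeline
(divide by $N_j$, scalar product with $v$) is re-applied, and the 95%
interval is the empirical 2.5/97.5 percentile over replicates.

Numerical choices, made once and deliberately:

* **Clamping.** Poisson draws are unbounded, so $k^*_{ij}$ is clamped at
  $N_j$ to keep every replicate probability in $[0, 1]$. This matters only
  for cells near saturation, where the upper CI limit correctly pins at 1.
* **Counts, not proportions.** The Poisson model is placed on
  mutated-sample counts with the observed count as mean — the natural
  scale for a count model, and the variance is then approximately the
  binomial variance whenever $p_{ij}$ is small, which is the regime of
  almost all panel genes.
* **Replicate-level propagation.** Intervals are computed on the weighted
  $P_i$ directly (re-applying the scalar product per replicate), not per
  cell and then propagated; this preserves the exact functional form of
  the estimator inside the bootstrap.
* **Percentile intervals.** No distributional formula is imposed on the
  replicate distribution; 2.5/97.5 empirical quantiles are used. The point
  estimate is not forced inside the interval by construction (it always is
  in practice except in degenerate all-zero cells).
* **Determinism.** One RNG stream, seeded once, replicate-major draw
  order: a fixed seed reproduces the interval table bit for bit.
* **Degenerate cells.** A gene with zero counts everywhere gets CI
  $(0, 0)$ — Poisson(0) is a point mass. No rule-of-three upper bound is
  substituted; that is a documented limitation for very rare genes.

The bootstrap's calibration is checked empirically in the test suite: over
500 regenerated synthetic datasets with true probabilities fixed in
$[0.05, 0.25]$ and 200 samples per site (moderate counts of roughly
10–50 per cell), the 95% intervals must cover the true weighted proportion
with empirical frequency between 0.92 and 0.98. Because the Poisson
variance exceeds the binomial variance by a factor $1/(1-p)$, intervals
become conservative as $p$ grows; the model is not recommended for genes
with per-site probabilities approaching 1 beyond the clamped upper limit.

## Tunable parameters

| Parameter | Default | Where | Why this default |
|---|---|---|---|
| `retain` (tier-2 classes) | missense, nonsense, frameshift, inframe indel, splice | `tier2Filter()` | the protein-altering set; frameshifts sit under the truncating umbrella — configurable because some panels count only substitutions |
| `nReps` | 2000 | `poissonCI()` | replicate count at which the 2.5/97.5 quantiles of these distributions are stable to well under a percentage point |
| `level` | 0.95 | `poissonCI()` | conventional coverage |
| `k` | 50 | `rankTopK()` | the comparison depth used for cross-population gene lists |
| `delta` | 0.10 (10 percentage points) | `classifyTp53Pattern()` | see below |
| `collapseDuplicates` | TRUE | `tabulateCohort()` | merged multi-repository studies can duplicate calls byte for byte |

## The TP53 pattern rule

Cancers are classified by where TP53 sits relative to the other top
genes. The rule: let $r_1$ be the highest per-gene rate and the *top
cluster* the genes with rate $\ge r_1 - \delta$. If the cluster is TP53
alone, the cancer is **TP53-Top**; if TP53 belongs to a cluster of two or
three genes, **TP53-Plus**; anything else is **Non-TP53**. "Clustered
with one or two other genes" is inherently fuzzy; fixing it as a rate-gap
rule with a named, reported $\delta$ makes the classification reproducible
and lets a user probe borderline cancers by varying one number. The
default of 10 percentage points separates gene pairs that practitioners
describe as co-dominant (e.g. an EGFR/TP53 lung adenocarcinoma profile at
59%/55%) from clear single-gene dominance (93% vs 30% in high-grade serous
ovarian profiles), and the label is invariant to everything below the
cluster threshold.

Rank ties anywhere in the package are broken alphabetically by symbol and
the tie rule is recorded in the output.

## Caller concordance

Per-caller gene lists are compared on the union of genes (a gene missed
entirely by one caller counts against concordance, rather than being
silently dropped). The multiway shared rate is
$|\cap \text{lists}| / |\cup \text{lists}|$; pairwise rates are the same
quantity per pair. The disagreement metric is the summed absolute pairwise
difference of per-gene patient counts, normalised by (number of pairs)
$\times$ (sum over genes of the per-gene maximum count). That denominator
is a declared design choice — it yields a scale-free fraction that is 0
exactly when all callers agree on every count and roughly "average
pairwise disagreement per patient-call" otherwise. Other normalisations
are defensible; the metric's absolute value should therefore be compared
only within one normalisation.

## What the generator emulates — and what it does not

`simTruth()` / `simCohorts()` produce multi-cohort MAF-style tables from
known per-site per-gene probabilities:

* probabilities are a mixture of a near-zero mass (Beta(1.2, 30), weight
  0.7) and a moderate mass (Beta(2, 6), weight 0.3), with the first gene
  (named TP53) drawn from Beta(8, 6) so one gene dominates, as TP53 does
  in real pan-cancer profiles;
* each mutated sample-gene pair emits $1 + \mathrm{Poisson}(0.15)$
  records, so accumulated rates (records per patient) strictly exceed
  prevalence for some genes, as observed for repeatedly-hit oncogenes;
* 5% of records are non-qualifying noise by default (silent, noncoding,
  SV, fusion, or off-panel symbols), and 5% of symbols are emitted as
  synonyms from a deterministic alias table, so the filtering and
  resolution stages have real work to do; both fractions are recorded in
  the truth object;
* two incidence-only sites keep the coverage gap $Q$ strictly positive;
* demographics are marginal draws — gender 50/50, smoking 30/60/10
  smoker/non-smoker/unknown — matching the stratification axes the
  comparison layer needs.

Not emulated: trinucleotide mutation spectra and signatures, copy-number
or structural-variant biology (beyond non-qualifying tokens),
demographic-dependent mutation probabilities, inter-gene correlation, and
cohort-level batch effects. Passing tests therefore demonstrate that the
estimator recovers known ground truth under the stated sampling model —
they do not validate representativeness of any real cohort, which is an
assumption the user must bring.

## Problem sizes used in the checks

The test suite exercises: exact pseudo-population equality of the scalar
product on instances up to 20 genes × 6 sites × 200 samples/site (tolerance
1e-12); parameter recovery at 2,000 samples/site with at least 95% of genes
inside 3 propagated binomial SDs; bootstrap coverage over 500 regenerated
datasets at 2,000 replicates each; 1,000 random weight configurations for
exact renormalisation; exhaustive overlap-identity enumeration for list
sizes up to 6 over a 10-gene universe. The acceptance script simulates a
382-gene × 23-site study at 520 samples per site (~12,000 patients), the
scale at which the full analysis is intended to run.

## Known limitations

* Registry weights are consumed as-is; no age-standardisation or
  registry quality control is performed or re-derived.
* Zero-count genes get degenerate $(0,0)$ intervals rather than a
  small-sample upper bound.
* The bundled synonym table is a small stand-in; for real analyses supply
  the synonym table matching your data sources (`readPanel()` accepts any
  two-column alias/official TSV, and ambiguous aliases are rejected at
  load time).
* Splice classification trusts the input dialect's splice classes;
  splice-distance thresholds are not re-derived from coordinates.
* The TP53 pattern rule and the concordance error normalisation are
  declared conventions, reported with their parameters, not community
  standards.
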