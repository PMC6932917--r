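---
title: "Methods: constellation partitioning, hub enrichment and semantic interrogation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constellation partitioning, hub enrichment and semantic interrogation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(constellatr)
```

## Scope

`constellatr` implements the informatic workflow used to characterize a
receptor's downstream signaling from stepwise ("constellation")
overexpression proteomics and affinity-purification interactomics:

1. **Constellation partitioning** — significance filtering of per-level
   protein quantification tables and multi-set Venn partitioning into
   unique/shared cells (`filterSignificant`, `vennPartition`,
   `uniquePercentages`, `commonCore`).
2. **PPI-hub enrichment** — exact hypergeometric enrichment of a query
   set against hub interactomes with the hybrid score
   H = k · (−log10 p), and ranking of expression levels by their
   enrichment for a hub panel (`hypergeomUpperTail`, `hybridScore`,
   `enrichSet`, `summarizeHubs`, `rankLevels`).
3. **Comparative interactome overlap** — exact overlaps of query
   interactomes with curated hub/disease gene sets, judged against
   size-matched random null sets (`setOverlap`, `nullDistribution`,
   `compareWithNull`, `overlapMatrix`).
4. **Latent semantic interrogation** — a gene-by-literature LSI engine:
   gene pseudo-documents, log-entropy weighting, truncated SVD, cosine
   interrogation with explicit/implicit thresholds, intersection
   ("theoretical") datasets and word/phrase frequency counting
   (`buildGeneDocuments`, `weightMatrix`, `fitLsi`, `queryCosine`,
   `interrogate`, `theoreticalDataset`, `countFrequencies`).
5. **Semantic ranking** — grouped cosine profiles (e.g. aging versus
   non-aging concepts), group contrasts, and the disease-continuum /
   therapeutic-interrogator percentile ranking (`cosineProfile`,
   `groupDifferenceTest`, `buildDiseaseContinuum`,
   `therapeuticCorrelationCounts`, `percentileHits`).

Everything runs on plain text inputs (GMT gene sets, TSV/CSV
quantification tables, JSONL corpora) or on the package's seeded
synthetic generators, so the full pipeline is testable without any
external database.

## Statistical model and conventions

### Significance filtering

A protein is called significantly altered at a level iff
p ≤ `maxP` and |log2 ratio| ≥ `minAbsLog2Ratio`. The source studies of
this kind rarely state their exact cutoff, so the criteria are explicit
configuration with conventional defaults `maxP = 0.05` and
`minAbsLog2Ratio = log2(1.2)` (a 1.2-fold change, a common choice for
iTRAQ ratios, whose dynamic range is compressed).

### Venn partitioning

`vennPartition` assigns each protein to the unique cell keyed by the
exact subset of levels containing it. Percent-unique values are
100 · |singleton cell| / |level set|, rounded **half-even** (IEC 60559,
R's `round`) at a configurable precision; published tables of this kind
print one decimal and sometimes truncate rather than round, so reported
agreement is expected to the last printed digit.

### Enrichment probability and hybrid score

The enrichment probability is the one-sided hypergeometric upper tail
P[X ≥ k] for X ~ Hypergeometric(N, K, n) — the convention of Fisher's
exact test as used by popular enrichment servers — computed exactly via
`stats::phyper`, never by normal approximation. The hybrid score is

H = k · (−log10 p),

defined as 0 when k = 0 (this avoids the 0 · (−log10 1) ambiguity), and
p is clamped to a floor (default 1e-300) before the logarithm so scores
stay finite. Two aggregations are reported over a target-hub panel
because the field's "sum of hybrid score occurrences" phrasing admits
both readings: the number of hubs enriched at `alpha`
(`occurrenceCount`) and the summed hybrid score (`hybridTotal`);
`rankLevels` orders levels by the latter with the former as tie-break.

### Size-matched random nulls

Observed overlaps are judged against `nSets` random sets of the query's
own cardinality, drawn without replacement from the collection's
universe. The empirical p uses the add-one estimator
(1 + #{samples ≥ observed}) / (1 + nSets), which is never 0 and is
bounded below by 1/(1 + nSets): with only 3 random sets — a design some
studies use — the smallest attainable p is 0.25, so small null
ensembles are descriptive, not inferential. The default is
`nSets = 1000`. Queries of equal size share one seeded null ensemble,
so adding queries never perturbs existing rows. The closed-form
hypergeometric moments (mean nK/N, the matching finite-population
variance) are used in the test suite to validate the resampler.

### The LSI engine

Genes are modeled as pseudo-documents: all documents tagged with a gene
are concatenated, giving a term-by-gene count matrix. The default
weighting is classical log-entropy — local log(1 + count) times the
global weight 1 + Σ_g p_tg log p_tg / log G — under which a term spread
uniformly over all genes carries no information (weight 0) and a term
confined to one gene carries full weight; smoothed tf-idf is available.
The weighted matrix is factorized by truncated SVD, and **both** term
and gene vectors carry the singular-value scaling (rows of U_k D_k and
V_k D_k). This symmetric convention is stated explicitly because it
fixes all cosines given the stored factors; at full rank the resulting
term-gene cosine equals the raw-matrix association cosine
(U D² V')_tg / √((WW')_tt (W'W)_gg), which the tests verify against an
independent eigendecomposition route. Component signs are fixed so each
component's largest-magnitude term loading is positive, making factor
output platform-reproducible.

Queries are tokenized (lowercase, split on non-alphanumerics, tokens
< 2 characters dropped), out-of-vocabulary tokens are dropped with a
warning, and the query vector is the sum of the constituent term
vectors. Cosine thresholds follow the literature-mining convention:
scores above 0.2 are explicit associations, scores in [0.1, 0.2] are
implicit, below 0.1 none. The boundary convention (0.2 and 0.1 both
classed implicit) is fixed here because the sources only state "larger
than 0.2" for explicit.

### Rank selection

For real corpora a truncation rank of a few hundred is the usual LSI
regime (`k = min(300, rank − 1)` is a sensible starting point). For the
package's synthetic corpora the tests run at **full rank**: the
synthetic term-by-gene matrix is nearly block-diagonal with hundreds of
near-equal singular values, and truncating such a spectrum mixes
arbitrary subsets of gene blocks, destroying planted-pair specificity
(measured: 0.42 at k = 50, 0.81 at k = 300, 0.98 at full rank). That is
a property of the synthetic spectrum, not a general recommendation;
real literature matrices have decaying spectra for which truncation
denoises.

### Disease continuum and percentile ranking

The continuum is the union over a battery of disease interrogator terms
of all genes at or above the implicit cutoff ("explicitly and
implicitly associated"; using 0.1 rather than 0.2 follows that
phrasing, and the cutoff is configurable). Per continuum gene, the
number of therapeutic interrogators with cosine ≥ `countingCutoff`
(default: the explicit threshold 0.2 — what counts as "a correlation"
is not standardized, so it is explicit configuration) is the
correlation count. Hits are genes whose count **strictly exceeds** the
nearest-rank q-quantile of the counts (default q = 0.99). Both the
quantile method and the strict inequality are stated because tie
handling changes hit counts on discrete data: on 1000 distinct counts
at q = 0.99 the rule returns exactly 10 hits, and when all counts tie
it returns none.

### Group contrasts

`groupDifferenceTest` compares per-gene **summed** scores over each
group's interrogators (the groups' term results added together per
gene) with a two-sided Student's t-test, equal-variance by default and
Welch as an option. The degenerate all-constant case reports t = 0,
p = 1.

## What the synthetic generators emulate

All generators are pure functions of their parameters including the
seed (one fixed RNG convention: Mersenne-Twister, inversion normals,
rejection sampling), and return their planted ground truth, making
exact parameter recovery the central testable property.

* `generateQuantTable` emulates a multi-level ratio table: per level a
  fraction of proteins (default 25%, of which 5 percentage points are
  shared across all levels) is planted with |log2 ratio| centred on 1.0
  (noise sd 0.25, resampled past the cutoff) and p below 0.05;
  the rest are null. `filterSignificant` recovers the truth exactly at
  the generator's thresholds by construction.
* `generateHubCollection` draws hub interactomes of fixed cardinality
  (defaults: the nine curated oxidative-stress/DNA-damage hub sizes
  198–301 used in the comparative analysis) from a synthetic
  20,000-gene universe, the scale of a whole-genome background.
* `generateInteractomePair` builds a 47-member control and a
  268-member stress interactome with exactly planted overlaps against
  mutually disjoint targets.
* `generateCorpus` emulates a gene-tagged abstract corpus at toy
  scale: 400 genes × 20 documents, a 4000-term vocabulary, planted
  gene-term pairs co-occurring with probability 0.8 (3 mentions per
  co-occurring document), every planted term appearing anywhere else
  with background probability 0.05 per document, and 20 filler tokens
  per document drawn from a gene-specific slice of the vocabulary.
  Gene-specific filler is deliberate: with a shared filler vocabulary
  the weighted matrix acquires a dominant all-positive singular
  component that inflates every term-gene cosine and no threshold
  separates planted from unplanted pairs. Under these defaults,
  planted pairs reach cosine ≥ 0.2 and non-planted pairs stay below
  0.1 with sensitivity 1.00 and specificity ≈ 0.98 (pooled over 100
  seeded corpora in the acceptance suite).
* `generateConstellationSets` deterministically builds level sets with
  exact totals, per-level unique counts and an all-levels core,
  filling the remainder with two-level cells (plus one three-level
  cell if parity requires and more than three levels exist) — the tool
  for reconstructing a partition from a published summary table when
  the underlying lists are not deposited.

What the generators do **not** emulate: MS-specific noise (isotope
impurity, iTRAQ ratio compression), correlated protein regulation,
Zipfian vocabulary, polysemy, or citation structure. Passing the
recovery tests therefore demonstrates the correctness of the
implementations under the stated statistical structure, not performance
on real corpora or real proteomes.

## Worked example

A miniature end-to-end run: plant a DNA-damage-response-enriched
"high" level, partition, and rank.

```{r example}
hubsUni <- sprintf("U%04d", 1:2000)
hubs <- GeneSetCollection(
    list(PRKDC = hubsUni[1:60], TP53 = hubsUni[61:120],
         PARP1 = hubsUni[121:180], TOP1 = hubsUni[181:240]),
    universe = hubsUni)
pair <- generateInteractomePair(
    controlSize = 50, stressSize = 80, collection = hubs,
    stressOverlaps = c(PRKDC = 15, TP53 = 12, PARP1 = 10, TOP1 = 8),
    seed = 6)
rankLevels(list(low = pair$control, high = pair$stress), hubs)
```

The planted level tops the ranking with a hybrid-score total far above
the unplanted one.

## Numerical choices and degenerate inputs

* Percentages and cosine thresholds are compared with half-even
  rounding at the stated precision; all internal computation is double
  precision, rounding only at the report boundary.
* `hybridScore` clamps p at 1e-300; `queryCosine` returns 0 for
  zero-norm query or gene vectors; `weightMatrix` removes all-zero
  rows and clamps entropy weights below 1e-12 to 0 so uniform terms
  are dropped exactly.
* Empty level sets make percent-unique undefined (error, not NA);
  an empty query after universe intersection is an error; fewer than
  two null sets leave the null sd undefined (NA with a warning).
* Ties: enrichment results order by (p, −hybrid, hub name); level
  rankings by (−hybridTotal, −occurrenceCount, label); percentile hits
  by (−count, gene label); frequency counts by (−count, item).

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely on synthetic data at
the scales the generators default to: 1000-protein × 5-level
quantification tables; a 20,000-gene universe with nine hubs of sizes
198–301; null ensembles of 1000 (10,000 where moments are checked
against closed forms); 400-gene × 4000-term corpora with 100 seeds for
the recovery rates; and a 10-disease-term × 300-gene continuum for the
percentile ranking. These sizes keep every planted effect comfortably
identifiable while the full suite completes in a few minutes.

## Known limitations

* The package does not reproduce numbers that depend on proprietary
  corpora or live databases (literature-wide interrogation sets,
  GO/KEGG p-values, platform-specific overlap percentages); it
  implements the methods that produced them.
* The LSI engine is a classical one (log-entropy + SVD); it does not
  model phrases beyond adjacent bigrams in frequency counting, and
  noun-phrase chunking is out of scope.
* With very small null ensembles the empirical p is bounded away from
  small values (see above); use the default 1000 sets for inference.
* Up/down-regulation signs are not partitioned separately in the Venn
  stage; cells are membership-only.
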