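---
title: "Methods: scoring, evaluating and aggregating gene prioritization strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, evaluating and aggregating gene prioritization strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priorank)
```

`priorank` ranks genes for targeted resequencing of cancer genomes and
measures whether a ranking is worth sequencing: whether its top is enriched
for somatically mutated genes relative to the baseline mutation rate of a
reference screen. This vignette documents the model behind each step, the
tunable parameters and their defaults, the numerical conventions, and what the
synthetic cohorts do and do not establish.

## Inputs and conventions

Five tabular inputs drive everything: a gene annotation (`gene_id`, `chrom`,
`start`, `end`), a logged expression matrix (genes × samples), segmented
copy-number profiles (SEG rows: sample, chromosome, interval, log-ratio
value), a mutation screen (mutated gene ids plus the total number of genes
sequenced), and a fitSNP DER lookup table (gene → value in [0, 1]).

Coordinates are stored 0-based half-open throughout; 1-based dialects are
converted at the reader boundary (`one_based = TRUE`), and BED input is taken
as already 0-based. Expression must arrive logged — the standard-deviation
score is only meaningful on a log scale — and `read_expression()` can apply
`log2(x + c)` (default offset `c = 1`, the microarray convention) to raw
matrices. Missing expression cells are an error by default; row-mean
imputation is available behind a flag but blurs the variance signal, so it is
never implicit.

## Gene-level copy number from segments

Segmentation output is piecewise-constant per sample; scores need one value
per gene. `assign_segment_values()` applies three rules, in order:

1. a gene overlapping exactly one segment takes that segment's value;
2. a gene overlapping several takes the value of the segment with the largest
   overlap length, ties broken toward the segment with the smaller start —
   a deterministic rule that favors no particular direction;
3. a gene overlapping none takes the value of the same-chromosome segment
   minimizing the interval gap (the nearest value). The fallback never
   crosses chromosomes: a chromosome absent from a sample's profile is an
   error unless `allow_missing_chrom = TRUE` marks those cells `NA`.

These rules (not a genomic-overlap library call) are the contract under test:
a brute-force "score every segment" oracle checks them on randomized genomes.

## The four scores

* **fitSNP DER** (`der_score()`): the table value, restricted to the gene
  universe; genes without a DER entry are excluded from the ranking rather
  than scored 0. An optional strict threshold (`min_der`) reproduces the
  classical 0.55 filter.
* **Expression variance** (`expression_variance()`): per-gene sample standard
  deviation with the n − 1 denominator — the unbiased-estimator convention,
  which matters at cohort sizes as small as 9.
* **Dosage sensitivity** (`dosage_sensitivity()`): Spearman correlation
  computed as Pearson on average ranks over the samples shared by both
  layers; at least 3 matched samples are required. Zero-variance vectors make
  the correlation undefined; such genes are scored `NA` and dropped from the
  ranking instead of being set to 0, so they cannot dilute the top of a list.
  `stats::cor(method = "spearman")` serves as an independent cross-check in
  the tests, not as the implementation.
* **Loss frequency** (`loss_frequency()`): the fraction of samples strictly
  below `loss_cutoff`. The cutoff is a per-dataset choice (platform and
  normalization dependent); the default −0.15 log2 ratio is a common
  single-copy-loss threshold for noisy array data. Values exactly at the
  cutoff do not count as loss. This score takes few distinct values
  (k / n_samples), so its rankings contain large tie groups — a practical
  weakness of the strategy itself, not of the implementation.

## Ranking and combination

`rank_genes()` orders descending by score with lexicographic (C-locale)
gene-id tie-breaks, making every ranking deterministic and independent of
input row order. Restriction to the sequenced universe is the default posture
for evaluation: PPV is undefined for genes the screen never sequenced.

Two strategies are combined (`combine_strategies()`) by finding the smallest
depth k at which their top-k lists share at least n genes, ordering that
intersection by rank sum, breaking ties by gene id, and truncating to n. The
smallest-k-then-rank-sum rule is a design choice: intersection defines only a
set, and this rule makes the combined list well-defined at every cutoff of
the evaluation ladder. Note the combined list is not nested across n — the
pipeline therefore builds one combined ranking at the largest achievable size
(capped at the largest cutoff) and evaluates it like any single ranking,
rather than re-intersecting per cutoff.

## Evaluation

All PPV arithmetic is exact fractions: `ppv()` returns an integer count over
k, so `k * ppv(k)` is always integral and PPV at the full universe equals the
baseline. The cutoff ladder defaults to 500, 400, 300, 200, 150, 100, 75, 50,
25, 10; cutoffs exceeding the ranking length are flagged unavailable, and the
mean PPV averages available cutoffs only. `max_ppv()` scans all k and reports
the smallest k attaining the maximum (an optional `min_k` excludes trivially
small lists, where a single mutated gene yields PPV 1). The baseline yield
count is the deterministic expected-yield ceiling — the smallest k with
k · rate ≥ m — rather than a sampling quantile; it is what "sequencing k
random genes yields k · rate mutated ones in expectation" prints as an
integer. Percent formatting rounds half-up to one decimal (2/7 → 28.6%).

`ppv_by_score_cutoff()` evaluates PPV among genes scoring strictly above a
threshold and accepts a list of mutation screens, pooled by union, for
calibrating a score threshold across tumor entities.

## Cross-dataset strategy aggregation

Each dataset orders the strategies (plus the baseline, as an item) by mean
PPV; the mean PPV doubles as the importance weight. The consensus minimizes
the weighted Spearman footrule — the sum over datasets and strategies of
weight × positional displacement. The footrule was chosen as the objective
because it is the standard brute-force aggregation target and is exactly
minimizable at this problem size; the weight convention (per-strategy mean
PPV within each dataset) is a stated choice, since "weighted by mean PPV"
fixes no formula by itself. Up to 8 items the optimum is found by full
enumeration with lexicographic tie-breaking; with 11 items (4 single + 6
combined strategies + baseline) enumeration costs 11! evaluations, so the
default is a seeded cross-entropy search over permutations (probability
matrix over item-position assignments, elite-fraction updates with smoothing
0.7), initialized with every observed ordering so the result is provably
never worse than the best observed list. Tests pin the heuristic to the
exhaustive optimum on ≤ 8 items. Datasets lacking any strategy (e.g. no
matched samples, hence no dosage sensitivity) are excluded from aggregation
with a warning.

## The synthetic cohorts

`generate_cohort()` emulates the statistical structure the analysis assumes,
not any particular tumor genome:

* mutation status is gene-level Bernoulli at the baseline rate (per-sample
  multiplicity is generated but unused, since evaluation is gene-level and
  most genes in small screens are mutated in a single sample);
* DER is Beta-distributed (concentration 7, null mean 0.3), with the mutated
  genes' mean shifted by `der_shift`;
* logged expression is normal per gene (mean ~ N(7, 1.5), SD ~ Gamma with
  mean 0.5), with mutated genes' SD multiplied by `var_ratio`;
* copy number is a two-state (loss/neutral) Markov chain along each
  chromosome with geometric run lengths matching `segment_length_mean`
  (default 5 Mb ≈ 50 genes at the fixed 100-kb gene spacing), loss segments
  at N(−0.6, 0.08) and neutral at N(0, 0.08). Mutated genes re-draw their
  state with loss odds multiplied by `loss_or`, and the next gene restarts
  the chain, so unmutated genes keep the base loss probability (default 0.1)
  exactly;
* for matched samples, a mutated gene's expression is mixed with its
  standardized copy number with weight `dosage_coupling`
  (`sqrt(1 − c²)·noise + c·cn`), giving a target correlation of c.

Defaults mirror a typical published entity: 18,000 genes at a 4.7% baseline
rate with 15 expression / 22 copy-number / 12 matched samples, and effect
sizes `der_shift = 0.25`, `var_ratio = 3`, `loss_or = 4`,
`dosage_coupling = 0.8` — strong enough that every strategy should beat the
baseline, which is the qualitative claim the enrichment-recovery tests
verify. All randomness flows from one master seed through fixed per-layer
sub-streams (mutations, DER, copy number, expression), so a seed pins the
bundle bit-identically and layers stay comparable across parameter changes.

What the generator does **not** emulate: realistic genome coordinates and
gene-length variation, probe-level noise and normalization artifacts, focal
versus arm-level aberration structure, hypermutated samples, subclonality,
and any correlation between the DER table and the expression matrix beyond
their common dependence on mutation status. Passing tests on these cohorts
therefore establish that the pipeline's arithmetic and its qualitative
parameter-recovery behavior are correct — not that any strategy will perform
comparably on a given real tumor entity.

## Problem sizes and numerical choices

The test suite and the acceptance script run cohorts of 700–3,000 genes
(18,000 only for the mutation-count law, with minimal sample counts), 100
replicates for the calibration and recovery checks, and 5–7 replicates with
common random numbers for the effect-size monotonicity grid — sizes chosen so
the full suite completes in about two minutes while keeping the binomial
bands narrow enough to be informative. Calibration uses the two-sided
binomial 99% band around each replicate's realized baseline for the top-100
mutated-gene count; the hypergeometric truth is slightly narrower, so the
band is conservative. Ties everywhere are broken lexicographically by gene
id; undefined scores are excluded rather than imputed; floating-point slop in
the baseline yield ceiling is guarded by an explicit integer check around the
division.

## Known limitations

* The loss-frequency score's coarse tie structure limits its resolution in
  small cohorts regardless of implementation.
* Combined lists depend on the (documented) intersection ordering rule;
  other reasonable rules (e.g. per-cutoff re-intersection) give slightly
  different per-cutoff PPVs.
* The cross-entropy search is stochastic: it is guaranteed no worse than the
  best observed ordering and empirically attains the exhaustive optimum on
  small instances, but global optimality at 11 items is not certified.
* Aggregation weights are within-dataset mean PPVs, so entities with high
  mutational burden influence the consensus more; no cross-entity
  normalization is applied.
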