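---
title: "Inferring mutational graphs from binary single-cell and multi-region data"
author: "mutgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring mutational graphs from binary single-cell and multi-region data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutgraph)
```

# The problem and the model

Sequencing several samples of one tumour — single cells, or spatially
separated bulk regions — gives a binary matrix `D` (`m` samples × `n`
somatic events) recording which alterations are present where. Under the
infinite-sites assumption (each alteration arises once and is not lost),
alterations are inherited along cell lineages, so an ancestor event is
present in every sample that carries any of its descendants. The target of
inference is a *mutational graph*: a directed acyclic graph over the events
whose edges state temporal precedence of acquisition. This is distinct from
a sample phylogeny (samples as leaves) and from a clonal tree (clones as
nodes); it is the event-level ordering those objects imply.

The central statistical idea is probabilistic causation: `x` is a
candidate temporal predecessor of `y` when

1. `p(x) > p(y)` (*temporal priority* — the ISA makes marginal frequency a
   proxy for age), and
2. `p(y | x) > p(y | ¬x)` (*association* — equivalent to
   `p(x, y) > p(x) p(y)`).

Both conditions are necessary, not sufficient; they prune the search space
to a *prima facie* graph from which an optimal tree/forest is extracted.

## Step 1: screening with a calibrated bootstrap test

All probabilities are empirical frequencies from `D` (after merging events
with bitwise-identical columns into aggregate nodes, whose internal order
is undecidable from binary data). The two conditions are assessed per
ordered pair on `B` bootstrap resamples of the samples. One set of
resamples is shared by all pairs, which preserves the dependence between
the statistics being compared: for a truly nested pair the within-replicate
difference `p(x)* − p(y)*` is non-negative in *every* resample of
noise-free data.

Each condition's p-value is the bootstrap probability that it is violated,
computed as the complement of the one-tailed Mann–Whitney U statistic of
the `B` within-replicate differences against zero (midrank ties):
`p = 1 − U/B`. Two properties motivated this exact form:

* **Type-I control.** Comparing the two bootstrap vectors *unpaired* (each
  against the other's distribution) miscalibrates badly: bootstrap
  distributions concentrate around the observed estimates, so any small
  observed imbalance eventually looks significant, and independent events
  acquire spurious orderings far above the nominal level.
  The within-replicate form is a standard bootstrap test: on independent
  Bernoulli columns its rejection rate is at the nominal level, and the
  prima-facie edge rate stays below `2·alpha` (both are asserted in the
  test suite).
* **Power on nested signals.** Pairing keeps the variance of the tested
  difference at the paired level, so high-frequency parent/child pairs
  with small marginal gaps remain orderable at realistic `m`.

Replicates in which the conditioning event is unobserved or ubiquitous
leave `p(y|x)` or `p(y|¬x)` undefined; they are dropped from the
association comparison, and a pair with more than half of its replicates
dropped is rejected outright (such an event carries no conditioning
information at this sample size). Identical columns give `p = 0.5` for the
temporal condition — no evidence — rather than an artificial rejection.

**Noise.** Genotyping error is asymmetric in SCS data (allelic dropout
makes false negatives dominate: `eps+ ≪ eps−`). When rates are supplied,
every marginal is corrected by inverting
`p_obs = p_true(1−eps−) + (1−p_true)eps+`, and every pairwise 2×2 joint by
the corresponding matrix inversion, clamped to `[0, 1]` and renormalised;
the correction is applied inside each bootstrap replicate. Rates are taken
as known a priori — no noise learning — which the noise-robustness scan
(`noiseRobustnessScan()`, a 5×5 grid around the true rates) supports:
specificity moves little under mild misspecification.

## Step 2: loop removal

With few samples some pairs cannot be unequivocally directed and the prima
facie graph may contain cycles, which an accumulation process forbids.
Every edge inside a non-trivial strongly connected component lies on some
cycle; the least confident such edge — confidence being
`1 − min(p_temporal, p_association)`, with weight and then lexicographic
`(from, to)` order breaking ties — is deleted, one per component per
round, until the graph is acyclic. Edges outside all cycles are never
touched.

## Step 3: model fitting

Edge weights are information-theoretic (base-2 logs; the base only
rescales weights and cannot change an optimum): pointwise mutual
information `log2 p(x,y)/(p(x)p(y))` of the co-occurrence cell (default),
or mutual information. A pair that never co-occurs has `pmi = −Inf`, a
sentinel ranked below every finite weight.

* **edmonds / gabow** compute the maximum-total-weight spanning
  arborescence per weakly connected component (recursive Chu–Liu
  contraction, and an iterative contraction-stack variant; both are exact
  and are cross-checked against exhaustive enumeration in the tests). Root
  placement is decided by the data via a virtual root connected to every
  node at a weight strictly below all real edges. Outputs have in-degree
  ≤ 1; `k` components yield `k` trees, the forest case covering polyclonal
  origin and unannotated initiating events.
* **chow_liu / prim** compute the maximum-weight undirected spanning tree
  of each component's skeleton (Chow–Liu re-weights it with mutual
  information — the classical factorisation of the joint distribution —
  Prim uses the graph's own weights), then direct every edge from the
  higher-marginal endpoint to the lower. Directing along that total order
  cannot create cycles but can give a node two parents (*confluence*),
  which expresses genuine uncertainty of precedence; outputs are DAGs.
  Equal-marginal pairs are unorderable from binary data: they are directed
  lexicographically for determinism and flagged `unknown_ordering`
  (rendered red/dashed in DOT output).

Model likelihood (`modelLikelihood()`) factorises the joint distribution
along the graph — Bernoulli marginals at roots, conditional Bernoulli
tables given the parents elsewhere — with parameters estimated from the
scored dataset by maximum likelihood. ML keeps the likelihood exactly
additive over samples and never hits `log 0` when a graph is scored on the
dataset its tables come from; a `pseudocount` argument provides smoothing
for cross-dataset scoring.

## Missing data

Missing entries (uncalled genotypes) are imputed by EM under an
independent-Bernoulli model per event: the E-step fills each `NA` with the
current marginal expectation, the M-step re-estimates marginals, iterating
to `tol = 1e-6` or 100 iterations; imputed datasets are then drawn by
sampling each `NA` from its converged expectation. Under this product
model the posterior of a missing entry given the sample's observed events
equals the event marginal — the model deliberately carries no dependence —
so dependence sensitivity is restored downstream: the full pipeline is fit
to each of `nImputations` completed datasets (default 100) and the model
with the highest graph-factorised likelihood on its own dataset is
returned (ties: total edge weight, then lexicographic edge set). Observed
entries are never modified.

# The synthetic-data generator

`sampleTopology(n, q)` draws a random recursive forest: `q` roots, each
later node attached to a uniformly chosen earlier node. Genotypes follow
exclusive branching lineages (`sampleSCGenotypes()`): a root is present
with its activation probability; below a present node one child is chosen
uniformly at random and becomes present with its own activation
probability, all other children and their subtrees are absent; recursion
stops at a sampled 0 or a leaf. This encodes the ISA (child ⇒ parent,
row-wise) and mutual exclusivity of sibling lineages, both asserted as
invariants over 10^4 sampled genotypes in the test suite.

Activation probabilities default to U[0.5, 1] per node. This is the one
genuinely open generator choice, and it matters: probabilities uniform on
[0, 1] routinely produce events with marginal ~10^-3 that occur in a
handful of cells out of a thousand, making parts of the truth
statistically unrecoverable at any realistic sample size and turning
recovery benchmarks into lotteries. The package's position is that an
event annotated in the input panel is there because it was detected at
callable prevalence, and that sorted single-cell samples carry founding
alterations in most cells; bounding activation away from zero encodes
exactly that, and makes large-sample consistency (asserted at `m = 1000`
in the tests) a property of the method rather than of the topology draw.
The bounds are arguments (`probMin`, `probMax`) for users who want harsher
regimes.

Multi-region data are emulated by pooling: each region draws
`cellsPerRegion` genotypes (default 10) and calls an event present when
more than a `threshold` fraction of pooled cells carry it (default 0.05;
both exposed, since bulk admixture parameters vary by assay). Noise flips
each 0 with probability `eps+` and each 1 with probability `eps−`
independently; missing entries are placed uniformly without replacement so
that exactly `floor(r·m·n)` cells are `NA`; confounders are i.i.d.
Bernoulli columns whose bias is drawn uniformly from the multiset of
observed event marginals (default count `round(0.1 n)`), emulating
miscalled variants with plausible frequencies.

What the generator does *not* emulate: doublets, read-level coverage and
VAFs, copy-number-driven loss of heterozygosity (no back mutation),
spatially structured sampling, or non-uniform missingness. Passing tests
therefore certify the statistical machinery under the stated generative
assumptions, not performance on data violating them.

# Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `alpha` | 0.05 | level of both screening tests per ordered pair |
| `B` | 100 | bootstrap resamples; p-value granularity is `1/B` |
| `weight` | `"pmi"` | pmi favours the direct parent among nested ancestors (`−log2 p(ancestor)` grows as the ancestor gets rarer) |
| `eps+`, `eps−` | 0, 0 | a priori error rates; must satisfy `eps+ + eps− < 1` |
| `nImputations` | 100 | completed datasets under missing data |
| `nBoot` | 100 | refits behind bootstrap edge scores |
| `cellsPerRegion`, `threshold` | 10, 0.05 | bulk pooling and presence calling |

# Evaluation harness

`sensitivitySpecificity()` scores an inferred model against the *direct*
parent→child edges of the generative truth over all ordered node pairs
(TP/FN on true edges, FP/TN on the rest; empty denominators score 1).
Direct-edge scoring is the strictest consistent reading of edge recovery
and is applied uniformly to all algorithms. Aggregate nodes are expanded so
every member inherits the aggregate's attachments (order inside an
aggregate is undecidable, so internal true edges count as misses);
confounders count as nodes with no true edges. `runScenario()`,
`noiseRobustnessScan()` (5×5 grid of input rates) and `missingDataScan()`
(r = 0…0.4 with round-robin noise arms and imputation-based fitting) wrap
the simulate→infer→score loop into tidy record tables.

Problem sizes in the shipped tests were chosen to finish a desk run in
minutes while keeping Monte-Carlo error small relative to the asserted
margins: recovery at `n = 11, m = 1000` over 20 replicates; 100 datasets at
`m = 50` (branching, noisy) and `m = 100` (forests, noise-free); the
missing-data design at 10 datasets × 5 missingness levels × 20 imputations.
The full-scale designs (100 datasets per cell, 100 imputations) are the
function defaults.

# Numerical choices and degenerate inputs

* Noise inversion is clamped to `[0, 1]` and joints renormalised; with zero
  rates the correction is exactly the identity.
* `0·log 0 = 0` in mutual information; `pmi = −Inf` is mapped to one unit
  below the smallest finite weight inside the spanning-tree/branching
  solvers.
* All tie-breaks are lexicographic on `(weight, source, target)` so every
  fit is deterministic given the data; RNG enters only through bootstrap
  resampling, the simulator and imputation draws, each governed by the
  caller's seed (the CLI fans one global seed out to independent per-stage
  seeds so adding a stage never perturbs earlier draws).
* Degenerate screening cases: single-column datasets give an empty graph;
  all-zero/all-one columns are reported by `validateDataset()` and cannot
  act as conditioning events (dropped-replicate rule); samples with no
  observed entries are reported rather than silently used.
* An entirely missing event column is imputed from the global marginal
  with a warning.

# Known limitations

* Binary input cannot order events with identical profiles (aggregates)
  or equal marginal frequencies (flagged `unknown_ordering`); allele
  frequencies would be needed for finer resolution.
* Screening power at `alpha = 0.05` bounds recoverable edges: events
  carried by only a few samples, or parent/child pairs separated by less
  than sampling noise at the given `m`, stay unresolved. With ~50 noisy
  cells this is the dominant loss mode for edge sensitivity, while
  specificity stays near 1 — the method under-claims rather than
  over-claims.
* No back mutation / ISA violations, no doublet model, no noise-rate
  learning; misspecified rates beyond the mild regime degrade results.
* The EM imputation model is independent per event; dependence enters only
  through likelihood-based model selection across imputations, which is
  effective to roughly 30% missingness in the shipped scan and degrades
  beyond.
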