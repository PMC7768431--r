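---
title: "Group-based semantic networks from verbal fluency data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-based semantic networks from verbal fluency data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluencynets)
```

## The problem and the model

Semantic verbal fluency data — lists of category members (typically animals)
produced in one minute — carry information about how concepts are organized
in semantic memory. Because a single participant's list is far too short to
estimate a network, `fluencynets` follows the *group-based* estimation
strategy: participants are split into two groups (for example by a median
split on a divergent-thinking or fluid-intelligence score), and one network
per group is estimated from the co-production structure of the group's
responses.

The estimator has four steps:

1. **Binarization.** Responses are cleaned (lemma normalization,
   category-lexicon filtering, within-participant repetition removal,
   removal of idiosyncratic tokens produced by fewer than two participants)
   and encoded as a participants × words incidence matrix with entries
   1/0.
2. **Equating.** Both group matrices are restricted to the tokens produced
   by at least two participants *in each group*, so the two networks share
   an identical node set and differences cannot be driven by node-set
   composition.
3. **Similarity.** For two word columns $A$ and $B$ over participants $j$,
   $\cos(A,B) = \frac{\sum_j A_j B_j}{\sqrt{\sum_j A_j^2}\sqrt{\sum_j B_j^2}}
   \in [0, 1]$. Cosine similarity never posits a negative association
   between two responses.
4. **Sparsification.** The dense similarity matrix is filtered with the
   Triangulated Maximally Filtered Graph (TMFG): a greedy planar filter
   that seeds the graph with the best 4-clique and repeatedly inserts the
   (node, triangular face) pair of maximal summed similarity, yielding a
   connected planar graph with exactly $3n-6$ edges and minimum degree 3.
   The filtered graph is then binarized; all downstream measures are
   defined on the unweighted graph.

Four measures summarize each network: the mean local clustering
coefficient (CC), the average shortest path length in hops (ASPL), the
Newman modularity (Q) of the best Louvain partition, and the
Humphries–Gurney small-world-ness
$S = (CC/CC_{rand})/(ASPL/ASPL_{rand})$, whose reference terms are means
over Erdős–Rényi $G(n,m)$ graphs with matched node and edge counts. $S$ is
about 1 for random graphs and well above 1 for small-world graphs.

## Statistical validation

Two complementary procedures are provided:

* **Null-model Z-tests** (`random_network_null()`, `z_test()`): 1000
  Erdős–Rényi graphs with the empirical node and edge counts are simulated;
  each empirical measure is compared to the resulting null distribution
  with a one-sample Z-test. Because the $S$ reference terms depend only on
  $(n, m)$, they are computed once per ensemble and shared across draws.
* **Graded bootstrap partial networks** (`bootstrap_partial()`): for node
  retention proportions 0.5–0.9, random node subsets (without replacement)
  are drawn; *the same subset* is applied to both group matrices, and each
  partial network is re-estimated from scratch (cosine → TMFG →
  binarization) rather than taken as an induced subgraph, preserving the
  $3n'-6$ invariant. Per proportion and measure, the two groups'
  `n_boot = 1000` values are compared with a pooled-variance two-sample
  t-test (df = 2·n_boot − 2) and Cohen's d. The t statistic is *low minus
  high*. Both sides of a realization share the Louvain restart seed, so
  identical inputs give exactly d = 0. A caveat inherited from the
  procedure itself: bootstrap realizations are treated as independent
  observations in the t-test although they are resampled from the same two
  matrices, so the printed p-values describe separation of the bootstrap
  distributions, not sampling uncertainty over participants.

Unique-response production is compared with McNemar's chi-squared test over
the full (un-equated) token universe: tokens produced only by the high
group ($b$) and only by the low group ($c$) are the discordant cells, and
$\chi^2 = (|b-c|-1)^2/(b+c)$ with the Edwards continuity correction —
the convention that exactly reproduces the worked reference values
(e.g. $b=45, c=24 \Rightarrow \chi^2 = 5.797$, $\varphi = 0.212$) — with
$\varphi = \sqrt{\chi^2/N}$.

## Behavioral scoring

`score_aut()` implements Alternative Uses Task scoring: fluency (number of
non-redundant ideas), flexibility (number of distinct idea categories),
idea-level creativity as the mean of two raters (1–5), the creativity sum,
and the overall divergent-thinking index ODT = creativity_sum/fluency +
flexibility. `icc_consistency()` returns both the single-measure and
average-measure two-way consistency ICC, because a two-rater consistency
ICC of a given magnitude can be reported in either convention and the
choice is not always stated; users should report which one they use.
`median_split()` breaks boundary ties by participant id after a stable
sort — an arbitrary but reproducible rule chosen because equal group sizes
under ties cannot be achieved otherwise. `correlate_indices()`
natural-log-transforms the skewed count-like indices before Spearman
correlation (falling back to `log1p` when zeros occur, as they can in
synthetic data); the transform does not change Spearman coefficients and is
applied for parity with common reporting practice.

## The synthetic study generator

Real child fluency data of this kind are not publicly deposited, so the
package ships a generator (`simulate_study()`) that emulates the study
conditions and provides known ground truth:

* a **planted-partition true network** (`make_true_network()`): by default
  140 words in 7 communities of 20, within-community edge probability 0.25,
  between-community 0.02, regenerated until connected. These defaults were
  chosen so that 58 simulated participants produce a token universe of
  roughly 120–140 words, the scale of the motivating data;
* **censored random walks** (`simulate_fluency()`): each participant walks
  the true network from a uniform start, moving to a uniform neighbour or,
  with teleport probability ε, to a uniform node, and emits a word the
  first time it is visited. List lengths follow a shifted Poisson
  (3 + Poisson(7), clipped), matching one-minute animal-fluency list
  lengths of about 10 (SD ≈ 2.6). ε operationalizes flexibility: higher ε
  blurs community structure in the co-production data, and the estimated
  network's modularity decreases monotonically in ε;
* **behavioral scores**: the grouping score is drawn from two
  non-overlapping uniforms (U(3,5) low, U(6,8) high) so a median split
  exactly recovers the generating groups; AUT component indices are
  monotone-plus-noise functions of it; covariates (words-per-minute,
  vocabulary, matrices score) are drawn group-independently so their group
  contrasts are null by construction.

**What the generator does not emulate.** Real fluency production is highly
Zipfian — a few animals are produced by nearly everyone and a long tail by
single children. The uniform-neighbour walk produces a much flatter
production distribution, so after per-group equating the synthetic node
sets are larger (≈50–70 words) than the ≈31–33 of comparable child data,
and group differences are diluted over more nodes. Passing tests on
synthetic studies therefore demonstrate that the pipeline recovers
walk-flexibility contrasts under these idealized conditions; they do not
certify effect sizes on real data. In our own calibration runs at 29
participants per group and 200 bootstrap realizations on 50% of nodes, the
qualitative flexibility signature (high-ε group: lower ASPL and Q, higher
S) was recovered in about 70% of independent study replications, with
Cohen's d around 0.3 — the same order as published 50%-retention values —
showing that between-study sampling noise at n = 29 per group is of the
same magnitude as the effect itself.

## Numerical and design choices

* **TMFG ties and seeding.** Ties in the seed-clique score and insertion
  gains are broken lexicographically by token order, making graphs
  bit-reproducible. The seed 4-clique is found exactly (all
  $\binom{n}{4}$ subsets) up to 25 nodes and by the top-weighted-degree
  heuristic above; empirical fluency networks sit near the boundary, so
  both paths are exercised routinely. Zero similarities are admissible edge
  weights; no thresholding is applied.
* **Clustering convention.** CC is the mean *local* (Watts–Strogatz)
  clustering coefficient with degree-<2 nodes contributing 0, not the
  global transitivity ratio.
* **Louvain restarts.** Louvain is vertex-order sensitive; `restarts = 10`
  permutations are run and the best-Q partition kept. On 30–60-node graphs
  this removes essentially all run-to-run variance.
* **Disconnected graphs.** TMFG output is always connected; for
  user-supplied or random graphs, ASPL is computed on the largest component
  with a warning, never silently infinite. At the densities used here
  (m = 3n−6) roughly 5% of $G(n,m)$ draws are disconnected.
* **Randomness.** Every stochastic routine takes a seed; nested procedures
  derive sub-seeds from the master seed with a counter-based map, so
  enlarging `n_boot` extends earlier draws instead of reshuffling them, and
  a pipeline run writes a byte-identical report bundle when repeated with
  the same configuration (no timestamps are written into outputs).
* **Rounding.** Bootstrap subset sizes use round-half-away-from-zero, so
  0.5 retention of an odd node count rounds up.
* **Problem sizes.** The shipped validation suites use 1000-graph null
  ensembles, 100-draw small-world reference ensembles, 200-realization
  bootstrap runs for simulation studies and 20 replication seeds — sizes at
  which the stochastic reference quantities are stable to the second
  decimal.

## Interface

The package is function-first: `run_pipeline()` executes the whole analysis
from a configuration list (or YAML/JSON file) — grouping, equating, network
estimation, null validation, bootstrap comparison, McNemar test — and
writes six report tables, graph exports (edge-list CSV and GraphML),
incidence matrices, a ground-truth JSON for synthetic runs and a run log.
No shell entry point is shipped; `run_pipeline()` plus small Rscript
wrappers cover scripted use.

## Known limitations

* The group-based estimator cannot characterize individual differences;
  it compares groups.
* The empirical small-world-ness of published fluency networks depends on
  the exact reference ensemble of the original software; with matched
  $G(n,m)$ references, random graphs score ≈1 by construction, but absolute
  S values are not comparable across reference conventions.
* The bootstrap t-tests inherit the independence caveat described above.
* The walk generator is a study stand-in, not a cognitive model fit to
  data.
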