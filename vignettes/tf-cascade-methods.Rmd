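---
title: "Methods: TF cascade extraction, ranking, enrichment and prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TF cascade extraction, ranking, enrichment and prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcascade)
```

## The problem

Transcription factors (TFs) regulate each other: one TF can activate or
inhibit the transcription of another, forming directed regulatory chains —
*cascades* — through which a perturbation at an upstream TF propagates to
downstream targets. This package reconstructs such cascades from a
protein-interaction action table, ranks the TFs that concentrate regulatory
flow, tests the cascades for pathway over-representation, assembles the
result into an attributed knowledge graph, learns node embeddings to score
candidate next-TF links, and compares survival between patients with and
without alterations in a candidate TF.

Every stage can be exercised offline against the bundled synthetic-data
generator, which plants known cascades, enriched pathways and survival
differences so that each analysis has a recoverable ground truth.

## Cascade extraction

**Edge filtering.** The input is a tab-separated action table in the STRING
`protein.actions` dialect (`item_id_a`, `item_id_b`, `mode`,
`is_directional`, `a_is_acting`, `score` with scores on the 0–1000 scale).
An edge is retained when (i) both endpoints are in the curated TF registry,
(ii) the combined confidence score is at least 700 ("high confidence"; the
boundary is inclusive), (iii) the interaction is directional, and (iv) the
mode is a regulation mode — activation or inhibition. Other STRING modes
(binding, catalysis, expression, ...) describe physical or indirect
relationships rather than a regulator→target assertion and are excluded;
`filter_tf_edges(modes = ...)` exposes the list for users who want the
broader reading (e.g. to include `expression`). The acting partner is the
regulator, so a record with `a_is_acting = FALSE` yields the edge B→A.

**Deduplication.** After protein→symbol mapping, exact duplicates
(regulator, target, mode) collapse to a single edge keeping the maximum
score — a deterministic, conservative resolution. Reciprocal pairs are kept
as two distinct directed edges. Self-loops created by many-to-one ID
mapping are removed and counted. Registry matching is exact-string after
upper-casing; alias expansion is deliberately out of scope for
reproducibility.

**Enumeration.** Cascades are simple directed paths rooted at *source*
nodes (in-degree 0), enumerated by depth-first search with visited-set
cycle pruning. Only *maximal* paths are emitted — a path is emitted when no
out-neighbour of its last node can extend it without revisiting a node —
because emitting every prefix would multiply counts without adding
information; `include_prefixes = TRUE` provides the alternative reading.
Components with no in-degree-0 node (pure cycles) yield no cascades and a
warning, and nodes unreachable from any source are reported. Out-neighbours
are visited in lexicographic order and the output is sorted
lexicographically, so results are identical across runs and platforms.
Because simple-path enumeration is exponential in the worst case, safety
caps (`max_length = 64`, `max_cascades = 1e6`) truncate loudly, never
silently.

A chain of *n* TFs has cascade level *n − 1* (the number of regulatory
steps), labelled `L{n-1}`; the wide cascade table stores one row per
cascade with `cascade_id`, the level label and one column per TF position,
positions beyond a cascade's length being structurally missing.

## TF ranking

**Extraction graph.** All cascades are united into one simple directed
graph whose edges carry an `occurrence_count` (number of cascades
containing the pair consecutively).

**PageRank.** The damped update
\(x'(v) = (1-d)/N + d \sum_{u \to v} x(u)/\mathrm{outdeg}(u)\)
is run for a fixed 10 iterations with damping 0.85 and every node
initialized to 0.25, with dangling-node mass redistributed uniformly. The
0.25 start vector does not sum to one; the procedure is run verbatim from
that start and the final vector is L1-normalized for reporting so scores
are comparable across graphs. `converge = TRUE` instead iterates to an
L1 tolerance of 1e-10 and agrees with `igraph::page_rank` to ~1e-8 on test
graphs.

**Centralities.** Degree is in+out degree. Betweenness is normalized
shortest-path betweenness on the directed graph. Closeness and eigenvector
centrality are computed on the undirected view by default: the extraction
graph is near-acyclic, and on such a graph directed eigenvector centrality
collapses to zero on all source nodes while directed closeness is undefined
for most ordered pairs; `directed_centrality = TRUE` gives the strict
variant. Closeness uses the Wasserman–Faust component-size correction
\(((r-1)/(n-1)) \cdot ((r-1)/\sum d)\) because extraction graphs can be
disconnected (igraph's closeness offers no such correction, so it is
applied from the distance matrix here). The eigenvector is taken from a
dense symmetric eigensolver rather than ARPACK: on these graph sizes the
cost is negligible and the result is deterministic, which the pipeline's
byte-identical-rerun guarantee requires; it is reported non-negative with
unit Euclidean norm.

**Prioritization.** A TF is flagged when it (i) sits in the top decile
(≥ 90th percentile, ties included) of at least two of PageRank,
eigenvector, closeness and betweenness, (ii) appears in at least
`min_cascades` cascades (default 1000, matching compendium scale; synthetic
runs pass a smaller value via the pipeline's `min_cascades`), and (iii) has
a non-zero alteration frequency in at least two cohorts — "multiple
cohorts" read as ≥ 2, configurable.

## Pathway enrichment

Over-representation uses the one-sided hypergeometric tail: with overlap
*k*, query size *n*, set size *K* and universe *N*,
\(p = P(X \ge k)\) for \(X \sim \mathrm{Hypergeom}(N, K, n)\), computed
with `phyper`. The odds ratio of the 2×2 table uses the Haldane 0.5
correction when any cell is zero. The z-score standardizes *k* by the
hypergeometric mean and variance, and the combined score is
\(-\ln(p) \cdot z\), the Enrichr-style combination; this z is a
closed-form stand-in for the web tool's rank-permutation z, so combined
scores are comparable within a run but are not a reproduction of any
external tool's values. Benjamini–Hochberg adjustment is the step-up
estimator (`p.adjust(method = "BH")`); the four-endpoint survival example
in the test suite shows why the step-up minimization matters (a naive
`p·m/rank` gives 0.0636 where the correct q is 0.0437). The default
universe is the union of the query/cascade genes and all library genes,
configurable — no background is imposed silently.

## Knowledge graph

The knowledge graph is a directed multigraph with TF and pathway nodes. Each
consecutive cascade pair contributes one TF→TF edge of weight 1, so pairs
shared by several cascades carry parallel edges; TF nodes carry their
`(cascade_id, level)` memberships. For every cascade whose enrichment
passes `p_adjusted <= alpha` (default 0.05), an edge runs from the
cascade's *terminal* TF to the pathway node — the terminal TF is the
cascade's convergence point, and linking it (rather than every member)
keeps the pathway side interpretable; the attributed edge carries p, z and
the combined score. The numeric edge weight is `1 − p_adjusted`, clipped to
[0, 1]: a convention chosen to be monotone in significance and bounded, not
an externally defined quantity. GraphML and JSON exports round-trip
losslessly; the TSV edge list is lossy by design.

## Link prediction

Node embeddings follow node2vec: second-order biased random walks (return
parameter *p*, in-out parameter *q*, both defaulting to 1, i.e. uniform
walks) with 10 walks per node of length 80, so the corpus always has
`num_walks × |V|` walks; walks traverse the graph as undirected, the
standard node2vec treatment (`directed_walks = TRUE` available). The walk
corpus trains skip-gram with negative sampling (dimension 128 by default,
window 10, 10 epochs, 5 negatives), implemented in C++ single-threaded with
its own RNG so embeddings are bit-reproducible given a seed. "Iterations"
names the training epochs; walk counts have their own parameter.

Link features come from four elementwise operators: Hadamard `u⊙v`, L1
`|u−v|`, L2 `(u−v)²` (squared difference — `l2_root = TRUE` gives the
rooted variant), and average `(u+v)/2`. Edges are split 75:25 with
uniformly sampled non-adjacent pairs as negatives (disjoint between train
and test, one per positive), a logistic classifier is fit on training link
features and ROC-AUC is reported on the test links per operator. The
default `holdout` mode trains embeddings on the training subgraph only;
`full` mode embeds the complete graph first, which leaks test edges into
the representation and should be read as an optimistic upper bound — the
package defaults to the honest protocol. Next-TF candidates are ranked by
cosine similarity to the cascade prefix's terminal TF.

## Survival comparison

Kaplan–Meier curves use the product-limit estimator via
`survival::survfit`, with the convention that events precede censorings at
tied times. The median is the smallest time with `S(t) ≤ 0.5`, without
interpolation (so a curve that touches 0.5 exactly reports that time), and
is undefined when the curve never reaches 0.5. Group comparison is the
standard unweighted log-rank test (`survival::survdiff`, 1 df). Q-values
across the four endpoints are BH step-up; BH is adopted because it exactly
reproduces the published four-endpoint q-values from their p-values — an
inference from arithmetic, as the adjustment method itself is not named in
the source tables.

## Synthetic-data generator

The generator emulates the six pipeline inputs with planted structure:

- **Interactions**: planted regulatory chains (default five chains of 4 TFs
  and two of 7, node-disjoint) emitted as directed activation/inhibition
  rows with scores in [700, 990]; optional noise adds extra TF–TF edges
  (directed with probability 0.9), sub-threshold and non-TF rows, binding
  rows and duplicate lines. Node-disjoint planting makes the planted chains
  exactly the maximal cascades of the noise-free graph, giving an exact
  recovery oracle; `allow_overlap = TRUE` relaxes this for stress tests.
- **Gene sets**: GMT library whose first sets contain all of their target
  TFs (recoverably enriched); the rest sample the universe uniformly.
- **Survival**: exponential event times with an unaltered median of 36
  months (a typical mid-range cohort median), altered-group rate multiplied
  by the hazard ratio (default 2, default altered fraction 0.15), and
  independent censoring (default 0.2); four endpoints per patient.
- **Alterations**: per-gene frequencies over 3 cohorts; ~30 % of genes
  altered per cohort, planted-path TFs always non-zero.

A fixed seed makes every artifact byte-identical across runs. What the
generator does **not** emulate: calibrated STRING score distributions,
correlated evidence channels, realistic pathway overlap structure,
non-exponential hazards, or cohort-level covariates. Tests passing on this
generator therefore demonstrate algorithmic correctness and closed-loop
recoverability, not performance on real STRING/cBioPortal data.

## Problem sizes and numerical choices

The test suite validates the enumeration against a brute-force oracle on
500 random DAGs of up to 12 nodes; PageRank and the centralities against
independent dense-matrix oracles on randomized 3–8-node graphs (agreement
to 1e-12) and worked small examples; hypergeometric p-values against
exhaustive subset enumeration for universes up to 20; and the stochastic
suites (link-prediction AUC on two-community vs Erdős–Rényi graphs,
log-rank calibration over 200 null replicates, KM median at n = 2000) at
sizes chosen to keep the full suite around a minute on a laptop-class
machine while leaving comfortable statistical margins. Embedding tests use
dimension 16–32 and 2–5 epochs; the package defaults (128/10) target real
analyses.

Other conventions: missing cascade-table cells are written as empty strings
in CSV; enumeration ties break lexicographically everywhere; PageRank
normalization is checked to 1e-9; the logistic classifier drops collinear
feature coefficients to zero rather than failing.

## Limitations

- Maximal-path enumeration is exponential in pathological dense graphs; the
  caps make this loud rather than fast.
- The enrichment z and combined score are closed-form conventions, not a
  reproduction of any web service's permutation statistics.
- The knowledge-graph edge weight is a package convention (monotone in
  significance); external weight scales cannot be compared to it.
- `full`-mode link-prediction AUC is optimistic by construction and is
  reported only to mirror the protocol of full-graph embedding studies.
- The dense eigensolver bounds practical extraction-graph size to a few
  thousand nodes; beyond that, an iterative solver with a fixed start
  vector would be the right extension.
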