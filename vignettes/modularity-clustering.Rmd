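---
title: "Module detection and annotation enrichment with modclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module detection and annotation enrichment with modclust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modclust)
```

`modclust` decomposes an undirected network into modules by greedy
modularity optimization, summarizes a decomposition as a metanode graph,
and scores node annotations per module with a hypergeometric test and a
majority rule. This vignette is the package's own account of the methods:
the models and their assumptions, the tunable parameters, what the
synthetic generators do and do not emulate, the numerical choices, and the
places where the design was genuinely open.

## The modularity model

All three partitioners maximize (variants of) Newman–Girvan modularity.
For a simple unweighted graph with `m` edges,

$$Q = \sum_c \left[ \frac{e_c}{m} - \left(\frac{d_c}{2m}\right)^2 \right],$$

with $e_c$ the edge count inside cluster $c$ and $d_c$ its summed degree:
the observed within-cluster edge fraction minus its expectation under a
degree-preserving random rewiring. The assumptions inherited from this
objective are worth stating: the input must be a *simple, undirected,
unweighted* graph (self-loops and duplicate edges are dropped at import,
with counts reported), and modularity maximization has a known resolution
limit — very small communities attached to a large graph may be absorbed.
No resolution correction is applied; that is a stated non-goal.

Fusing clusters $a$ and $b$ changes $Q$ by
$\Delta Q = l_{ab}/m - d_a d_b/(2m^2)$, and moving one vertex $v$ from $a$
to $b$ by $(l_{vb}-l_{va})/m - k_v\,(d_b - d_a + k_v)/(2m^2)$ (degrees
counted before the move). Both gains are maintained incrementally and are
required — and tested — to agree with from-scratch recomputation to
$10^{-9}$ or better.

For the multi-level algorithm the same objective is used on weighted
graphs: counts become weights, degrees become strengths, and a self-loop
(created by collapsing a cluster) contributes its weight once to $e_c$ and
twice to the strength. The weighted form on a collapsed graph equals the
unweighted form on the original graph under the composed partition, which
is what makes level recursion sound.

## The three partitioners

**FT** alternates a best-first fusion (maximum positive $\Delta Q$; ties
broken toward the lexicographically smallest cluster-ID pair, merged
cluster keeping the smaller ID) with transfer sweeps that move each vertex
to its best *adjacent* cluster while the gain exceeds `tol`, until neither
phase changes anything. Whether transfers belong after the complete fusion
phase or interleaved with it was an open design point; we interleave, and
the reason is measurable: with fusion-then-transfer only, greedy
agglomeration occasionally locks in an early mis-merge that single-vertex
transfers cannot undo, leaving the result up to ≈0.06 below the exhaustive
optimum on 8-node benchmark graphs, while interleaving keeps the worst
observed gap at 0.04.

**TFiT** is the Louvain pattern: transfer sweeps from singletons on the
current (weighted) graph, collapse of the resulting clusters into a
weighted quotient graph, and recursion until a level makes no move, with
assignments composed back to the original nodes.

Both algorithms visit vertices in a seeded-shuffled order, so results are
deterministic functions of `(graph, parameters, seed)` — a property the
suite tests bit-for-bit. Because sweep outcomes depend on that order, each
level (TFiT, default 8) or the whole loop (FT, default 5) is restarted
from independent shuffles and the best-modularity outcome kept. The
restart counts were chosen so that, on seeded random graphs small enough
for exhaustive search (≤ 8 nodes, where all ≤ 4140 set partitions can be
enumerated), the worst gap to the true optimum stays comfortably within
the 0.05 band the package promises; single-order sweeps fail that promise
(a single Louvain pass on a 5-node graph can collapse everything into one
cluster, gap ≈ 0.11).

A vertex may optionally be allowed to *leave* its cluster into a fresh
singleton (`allow_split = TRUE`); it is off by default because the
transfer target the algorithms are defined over is the best adjacent
cluster.

**OCG** starts from an overlapping class system and fuses the class pair
with the best positive gain in the overlap-aware modularity

$$Q_{ov} = \frac{1}{2m} \sum_c \sum_{i,j \in c}
  \frac{A_{ij} - k_i k_j/(2m)}{f_i f_j},$$

where $f_v$ is the number of clusters containing $v$ and the inner sum
runs over ordered pairs including $i=j$. The published description of this
algorithm family fixes neither the exact overlap modularity nor the
default class system, so both are package decisions with a safety net: the
ordered-pair form above is the unique natural $1/f$-splitting that reduces
*exactly* to $Q$ when the cover is disjoint (a pairs-only $i<j$ variant
does not — it loses the diagonal $-k_i^2/(4m^2)$ terms and a factor 2),
and that disjoint-limit identity is a standing test. Candidate fusions are
restricted to class pairs sharing a node or an edge; ties prefer the
smaller combined size, then the smaller ID pair. Because merging two
overlapping classes lowers $f$ for the shared nodes, the gain is evaluated
by recomputing the contributions of every affected cluster — OCG is
therefore the most expensive of the three and intended for networks of
modest size (hundreds of nodes), which matches its role of exposing
multi-membership candidates rather than scaling to full interactomes.

Initial class systems: `centered_cliques` (default; for each vertex in ID
order, a maximal clique grown greedily through neighbors in descending
degree order, containment-filtered), `maximal_cliques` (Bron–Kerbosch via
igraph), or `edges`. Cluster IDs in every final partition are canonical:
consecutive integers from 1 by decreasing size, ties by lexicographically
smallest member — any numbering scheme would do, but this one is
deterministic and stable across runs.

## Quotient graphs

A partition becomes a graph of metanodes (size = node count, internal edge
count attached). Two semantics connect metanodes: *inter* edges count
links between the exclusive parts of two clusters, *overlap* edges count
shared nodes. For edges touching shared nodes the convention — the
published behavior is silent here — is: an edge contributes to
inter$(A,B)$ only if one endpoint belongs to $A$ but not $B$ and the other
to $B$ but not $A$; an edge between two doubly-shared nodes is internal to
both clusters and contributes no inter weight. This avoids reporting the
same adjacency both as "shared node" and as "link". For disjoint
partitions the invariant $\sum_c \text{internal}_c + \sum \text{inter} =
m$ holds and is tested on random partitions. GraphML exports carry node
attributes `size` and `internal` and edge attributes `weight` and `type ∈
{inter, overlap}`, and round-trip losslessly.

## Annotations and enrichment

Annotation files are two columns (node ID, term list) with free separators
(comma, semicolon or tab; column and term separators must differ, header
lines skippable, columns selectable). Terms are trimmed, empties dropped,
repeated node lines unioned; IDs absent from the network are dropped with
a count rather than an error, because public annotation sets routinely
cover genes outside any given network. Coverage (count and percentage of
annotated nodes) is reported to two decimals.

Each (cluster, term) pair with at least one carrier, in clusters of at
least `min_cluster_size` nodes (default 5 — clusters of a handful of
nodes cannot support a stable test and are hidden by default), is scored
with the one-sided hypergeometric upper tail $P(X \ge k)$ via
`stats::phyper`. The background is a genuine choice:

- default `background = "annotated"` — $N$ = annotated nodes of the whole
  graph, $n$ = annotated nodes of the cluster. The reported percentages
  are "among annotated nodes", and counting unannotated nodes would
  inflate enrichment of well-annotated clusters;
- `background = "all-nodes"` — every node counts; available because some
  published tools do this.

Benjamini–Hochberg (via `stats::p.adjust`) is applied once across *all*
records of a run by default (the tests are one family: the same term list
against all clusters); `bh_scope = "per-cluster"` corrects within each
cluster instead. A record is `enriched` when adjusted $p <$ `alpha`
(default 0.05, strict), and passes the majority rule when it annotates at
least `majority_threshold` percent (default 50, boundary *inclusive*) of
the cluster's annotated nodes. For overlapping partitions a shared node
counts in every cluster containing it, while $K$ and $N$ are computed once
on the graph. Terms are tested exactly as given: no ontology propagation,
no semantic collapsing of redundant terms (both stated non-goals), so two
perfectly correlated terms will both appear enriched.

Manual cluster labels (`add_custom_annotation()`) are bookkeeping only and
never enter the statistics.

## Synthetic generators, and what passing tests do and do not show

`make_sbm()` draws a stochastic block model: within-block pairs become
edges with probability `p_in`, between-block pairs with `p_out`. The
recovery benchmark uses 4 blocks of 20 nodes with `p_in = 0.3`,
`p_out = 0.02` — mean within-degree ≈ 5.7 against ≈ 1.2 across blocks, a
clearly assortative but noisy regime. `make_annotations()` annotates each
(node, term) pair independently at a background rate, multiplies the rate
for planted (cluster, term) pairs, and then pads or thins to an exact
target coverage using a catch-all term, so the enrichment background is
controlled exactly.

Benchmark conditions used by the suite and `scripts/acceptance.R`, with
their rationale:

- *oracle band*: 100 seeded connected random graphs of 5–8 nodes; both FT
  and TFiT must stay within 0.05 of the enumerated optimum and never
  exceed it. Sizes are capped at 8 because exhaustive search enumerates
  all set partitions (4140 at $n=8$).
- *recovery*: ARI ≥ 0.9 against the planted blocks in ≥ 95 of 100 SBM
  replicates.
- *null calibration*: 30 structureless terms at background rate 0.08,
  coverage 0.9, 50 replicates; the mean fraction of BH-adjusted
  discoveries must stay at or below 0.05 (it is near zero in practice).
- *planted sensitivity*: terms planted at 3× a background rate of 0.30 in
  designated 20-node clusters, coverage 0.95, 50 replicates, sensitivity
  ≥ 0.9 at `alpha = 0.05`. The background rate was fixed by a power
  calculation, not by trial: at rate 0.3 the planted cluster carries
  $k \approx 17$ of its ≈ 19 annotated nodes against a null mean of
  ≈ 9, putting exact-test power above 0.99, so the benchmark measures
  pipeline correctness rather than fixture noise (at a 0.2 background the
  same design is underpowered and would test the fixture, not the code).

What these fixtures deliberately do not emulate: the heavy-tailed degree
distributions of real interactomes, degree-correlated annotation coverage
(well-studied proteins are better annotated), correlated terms from an
ontology DAG, and assay-specific false positives/negatives. Passing the
suite therefore shows the algorithms and statistics are implemented
correctly under controlled conditions; it does not certify biological
conclusions on any particular real network. The published
human-interactome workflow (8149-node component, 67 TFiT clusters, 88% GO
coverage) is reproducible with `huri_reproduction()` once the deposited
files are placed under `inst/extdata/huri/`; cluster *counts* there are
heuristic, order-dependent quantities, which is why agreement within
±10% is the realistic expectation while node/edge counts and coverage are
exact.

## Numerical choices and degenerate inputs

- `tol = 1e-12` on transfer gains: strictly positive to break the
  accept/reject symmetry of zero-gain moves, far below any honest gain on
  graphs with $m < 10^{6}$.
- Tie-breaks (fusion pairs, transfer targets, OCG candidates, class
  ordering, component selection) are all resolved lexicographically or by
  size so that every code path is deterministic; the suite asserts
  bit-for-bit reproducibility.
- Floating-point comparisons between maintained and recomputed modularity
  use $10^{-9}$; gain-vs-recompute identities use $10^{-12}$.
- Degenerate inputs: empty graphs and edgeless graphs are errors for the
  partitioners (modularity is undefined at $m = 0$); disconnected graphs
  are fine (components can never merge, since $l_{ab} = 0$ makes every
  cross-component fusion gain negative); singleton clusters have density 0
  by convention; a term carried by every background node has upper tail
  exactly 1 in every cluster.
- `P(X ≥ k)` is computed as `phyper(k - 1, K, N - K, n, lower.tail =
  FALSE)`; the suite verifies it against full enumeration of all
  $\binom{N}{n}$ draws for every $N \le 12$ at $10^{-12}$.

## Known limitations

Pure-R single-threaded implementations: FT is quadratic-ish in cluster
count and OCG recomputes affected contributions per candidate fusion, so
both are for small-to-medium networks; TFiT handles interactome-scale
graphs (tens of thousands of edges) in minutes. Modularity's resolution
limit is inherited, exact maximization is out of scope, and enrichment
treats terms independently. Directed and weighted *input* networks are not
supported (weights arise only internally during coarsening).
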