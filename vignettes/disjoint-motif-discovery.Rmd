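---
title: "Disjoint motif discovery: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disjoint motif discovery: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disjointMotifs)
```

## The problem

A *motif* is a topological pattern that recurs in a network more often than
a frequency threshold. In protein--protein interaction (PPI) networks and
other biological graphs, motifs are read as functional building blocks, so
both their identity and their abundance matter. The difficulty is how to
*count*. The classical F1 measure counts every embedding of a pattern,
overlapping or not. F1 inflates counts (a single hub edge can participate in
hundreds of embeddings) and, worse, it is not *downward closed*: a pattern's
F1 count can go up as the pattern grows, so no growth-based search can prune
early or decide that it has found the largest frequent motif.

This package therefore counts **disjoint** copies:

* **F2** -- the largest set of embeddings of a pattern that pairwise share
  no *edge*;
* **F3** -- the stricter variant in which embeddings may not share a *node*.

Both are downward closed: if a pattern `M` is a subpattern of `M'`, then
`F2(M) >= F2(M')` (delete the extra edges of each disjoint embedding of `M'`
and you obtain that many disjoint embeddings of `M`). The suite verifies
this monotonicity against an exact solver on random graphs.

## Data model

A network is a simple undirected graph (`MotifNetwork`) over opaque string
node identifiers -- PPI files carry protein accessions, so no integer
re-indexing is exposed. Self-loops and parallel/reversed duplicate edges in
input files are normalised away with a warning rather than rejected, because
real interaction files contain them. An *embedding* is identified purely by
its edge set; we store it as a sorted vector of canonical edge keys
(`"u v"`, endpoints in lexicographic order), which makes duplicate detection
exact and tie-breaking reproducible. An *equivalence class*
(`EquivalenceClass`) is a pattern together with all its stored embeddings
(the F1 support) and the currently selected disjoint subset.

Before discovery, connected components with fewer nodes than the motif size
are removed (`pruneSmallComponents`); they cannot host a motif of that size.

## The discovery algorithm

Four **basic building patterns** seed the search: the 2-edge path (M1), the
triangle (M2), the 3-star (M3) and the 3-edge path (M4) -- exactly the
connected topologies with two or three edges (the suite proves this by
exhaustive enumeration). Any connected pattern with four or more edges can
be built by repeatedly joining a smaller pattern with one of these four,
where two embeddings *join* when they share at least one edge and their
union is strictly larger. Disjoint embeddings of a single pattern never
share an edge, which is why one pattern class alone cannot grow itself and
a small basis of several classes is needed.

One iteration of `findMotifs`:

1. every motif instance in the current classes' disjoint sets is joined with
   every basic-pattern instance sharing an edge with it;
2. each product is classified into an equivalence class through the filter
   cascade (below), opening a new class for an unseen topology and
   discarding exact duplicates;
3. every touched class is recounted (greedy disjoint extraction) and classes
   below the threshold `alpha` are deleted -- downward closure guarantees
   they can never become frequent again.

Classes whose pattern reaches the target size are harvested; products
exceeding it are discarded immediately. The run stops when an iteration
leaves no class below the target, with a safety cap of `mu` iterations
(each join adds one or two edges). Because joins start from *disjoint*
instance sets, the search is sound but not complete: every reported pattern
and embedding exists in the graph, but not every embedding of every pattern
is necessarily found. `validateMotifReport` asserts soundness (host edges,
connectivity, isomorphism to the reported pattern, pairwise disjointness,
and the packing bounds `frequency x edges <= |E|` / `frequency x nodes <=
|V|`) on every report.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `mu` | -- | target motif size; nodes (default) or edges per `sizeMode` |
| `alpha` | 1 | minimum disjoint frequency (count, unitless) |
| `measure` | `"F2"` | edge-disjoint or node-disjoint (`"F3"`) counting |
| `joinSource` | `"disjoint"` | basic instances fed to joins |
| `nRandom` | 100 | shuffled replicas for the ensemble z-score |
| `swapFactor` | 10 | successful double-edge swaps per edge |

`joinSource = "disjoint"` follows the published algorithm (only the F2-count
survivors of each basic pattern feed the joins) and is cheapest.
`"all"` feeds every enumerated basic instance instead; on small or highly
overlapping graphs this recovers embeddings the disjoint seed set misses
(on the seven-node worked example it is required to see all three
embeddings of the 4-edge chordal pattern), at higher cost. Both are exposed
because recall and cost trade off differently at PPI scale versus toy scale.

## Counting disjoint embeddings

Extracting a maximum independent set (MIS) of the *overlap graph* -- one
node per embedding, edges between overlapping embeddings -- is NP-complete,
so two greedy heuristics are used:

* **Explicit overlap graph** (`buildOverlapGraph` + `greedyMIS`), for
  derived patterns with short embedding lists: repeatedly select the node
  with minimum current degree, delete it and its neighbours, update
  degrees. Minimum degree first is the choice that favours large
  independent sets.
* **Algebraic single pass** (`greedyMISAlgebraic`), mandatory for the four
  basic patterns, whose embedding lists are the largest by far: each
  embedding's overlap count is computed *algebraically* from host-graph
  degrees, adjacency and common-neighbour counts; embeddings are processed
  in ascending overlap order and accepted whenever they touch no used edge
  (F2) or node (F3). No pairwise embedding comparison or adjacency list is
  ever built. The accept/reject scan replaces explicit neighbour deletion;
  its output is still an independent, maximal set (asserted in the tests),
  which is what the frequency semantics require.

For an M1 embedding `{(a,c), (b,c)}` with centre `c`, the edge-overlap
count is the closed form `2 d(c) + d(a) + d(b) - 6`: every further edge at
the centre creates two overlapping 2-paths, every further edge at a leaf
one. The remaining seven pattern/measure combinations were derived for this
package by inclusion--exclusion over the embedding's edges (F2) or nodes
(F3), with per-term counts expressed through degrees, adjacency indicators
and common-neighbour counts. Examples: triangles overlapping a triangle
`{a,b,c}` under F2 number `cn(a,b) + cn(a,c) + cn(b,c) - 3` (two distinct
triangles can share at most one edge); 3-stars overlapping a star with
centre `c` and leaves `L` under F2 number
`C(d(c),3) - C(d(c)-3,3) - 1 + sum over l in L of C(d(l)-1, 2)`. The
node-overlap (F3) cases run inclusion--exclusion over the 3 or 4 embedding
nodes, with terms such as "number of 3-edge paths containing two prescribed
nodes" resolved by case analysis over the nodes' positions in the path.
Every one of the eight count functions is validated against a brute-force
overlap oracle over all embeddings of 50 random scale-free graphs in the
test suite; that equivalence is part of the acceptance criteria, not just a
development aid.

## Avoiding isomorphism tests

Each join product must be assigned to an equivalence class; the exact
subgraph-as-graph isomorphism test (backtracking over degree-compatible
bijections) is the expensive last resort. Two isomorphism-invariant labels
filter first:

1. the **degree vector**, the sorted degrees within the pattern;
2. the **nodes vector**: with `x` the pattern diameter, `x_ij` the
   within-pattern distance and `d(v_j)` the within-pattern degree, node `i`
   is labelled `sum over j of 2^(x - x_ij - d(v_j))`, and the sorted labels
   are compared.

The label sum runs over *all* nodes including `j = i` (with `x_ii = 0`);
reading the sum as excluding the self term would also be a valid invariant,
but the literal reading is used and documented here. Labels are dyadic
rationals, so exact comparison would work; an absolute tolerance of 1e-9 is
used anyway to guard accumulated floating-point error. Patterns are
compared as bare edge sets (non-induced semantics): a 4-edge path whose
endpoints happen to be adjacent in the host graph is still a path, because
the embedding is its edge set. No full canonical form is computed -- the
filters plus the exact test are sufficient, and on matched non-isomorphic
scale-free pairs the degree vector alone resolves well above 85% of cases
(measured by `scripts/acceptance.R`).

## Significance of motif abundance

Two z-scores for the most abundant motif of a given size:

* **within-graph**: against the frequencies of all motifs of that size in
  the same graph, `z = (x1 - mean) / sd`;
* **ensemble**: against the top frequency in each of `nRandom` (default
  100) random networks obtained by *degree-preserving edge shuffling* --
  pick two edges `(v1,v2), (u1,u2)`, replace them with `(v1,u2), (u1,v2)`,
  reject proposals creating self-loops or parallel edges, and count
  `swapFactor x |E|` (default 10x) *successful* swaps.

`|z| > 2` is flagged significant. Choices made where the procedure was
underspecified: the standard deviation is the sample sd (n-1 denominator);
swap proposals are retried within a bounded budget (ten times the target,
at least 100 |E|) so the randomisation depth is guaranteed, with a warning
when a graph admits too few valid swaps; per-replica RNG streams are
derived from `(seed, replica index)` so replicas are reproducible and
independent; and the within-graph frequencies are computed with `alpha = 1`
so every motif of the size is seen. When all reference frequencies are
equal the score is reported as undefined rather than infinite.

## Synthetic data

`barabasiAlbert(n, density, seed)` emulates PPI-like scale-free
connectivity by preferential attachment: density 1--4 edges per arriving
node covers the range of biological networks, and density 2 (mean degree
about 4) matches the synthetic setting used for the filter-rate experiment.
Initialisation is a clique of `density + 1` nodes -- the model's initial
condition is a free choice and filter rates are robust to it; the clique
start keeps every early node attachable and the edge count exactly
predictable. `fig1Graph()` is the fixed seven-node, eight-edge worked
example. `nonisomorphicPairs` draws matched-size BA pairs (node counts
uniform in 20--60, density 2 by default; the experiment's exact parameters
are a package choice, recorded in the function defaults) and rejects the
rare isomorphic pair via an exact check.

What a green test on these generators does establish: correctness of the
counting machinery (validated against brute-force and exact oracles),
soundness of every report, and the stated behaviour of the filters on
scale-free topology. What it does not establish: recall on dense real PPI
networks, which depends on the joinSource trade-off above, nor the
published absolute runtimes, which are hardware-bound.

## Numerical and procedural choices

* Tie-breaks everywhere (greedy selection order, report order) fall back to
  lexicographic canonical keys, so identical inputs give byte-identical
  reports.
* The two sources in the published description disagree on whether
  embeddings are processed in increasing or decreasing overlap order; this
  package processes *ascending* (minimum overlaps first) in both
  heuristics, consistent with the explicit min-degree greedy and with
  maximising the independent set.
* Disjoint sets are re-extracted from scratch each iteration rather than
  updated incrementally; with embeddings accumulating across iterations an
  incremental update could retain a no-longer-maximal selection.
* Products may not join again within the iteration that created them: one
  growth step per iteration keeps the iteration semantics (and the
  iteration cap) well-defined.
* Harvesting happens at iteration end; in node-counting mode a class is
  harvested exactly when it reaches `mu` nodes, so denser same-node-count
  variants are reached through joins that add edges without adding nodes
  (products never exceed `mu`).
* An empty result is valid (exit code 2 from the CLI), distinct from a
  usage or I/O error (exit code 1).

## Known limitations

* No completeness guarantee: joins grown from disjoint instance sets can
  miss embeddings; `joinSource = "all"` mitigates but does not remove this.
* The greedy MIS is a lower bound on the true disjoint frequency (equality
  on most small instances, verified against branch-and-bound).
* Directed and weighted graphs, node/edge labels, and approximate or
  sampled counting are out of scope.
* The within-graph z-score requires at least two motif classes of the
  requested size; on very small graphs discovery may return only one.
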