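---
title: "Compartment-annotated network analysis: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-annotated network analysis: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capnet)
```

## The model

`capnet` treats a signaling system as an undirected graph: nodes are
molecules, molecular species or discrete events (e.g. a membrane-fusion
step), and an edge records that two of them interact or that one drives
the other. Each node carries a subcellular-compartment label from a
declared vocabulary (by default membrane, cytosol, cytoskeleton,
mitochondria, acrosome, nucleus, extracellular). Undirectedness is an
assumption, not an afterthought: curated signaling maps mix causal arrows
with physical bindings, and the questions this package asks — who is a
hub, whose neighborhood spans the districts, what detaches when a node is
deleted — are questions about connectivity, for which direction is
ignored.

### Raw interactions vs. the simple view

Interaction lists exported from curation tools routinely contain
duplicated pairs (the same link curated from two sources, or entered in
both orientations) and occasionally self-loops. Neighbor-based statistics
silently collapse these, which is why a network whose reported edge count
is `E` can have a mean neighbor count smaller than `2E / N`. `capnet`
makes the distinction explicit: every network carries its raw interaction
multiset, all topology statistics are computed on the **simple view**
(self-loops dropped, parallel and reversed duplicates collapsed), and
reports show both `n_interactions_raw` and `n_edges_simple`. Degree
always means *distinct neighbors*.

## The statistic bundle

For a network with simple-view degree `k(v)`:

* **Local clustering**: `C_v = 2 n_v / (k (k - 1))`, with `n_v` the number
  of links among the `k` neighbors of `v`. The formula is undefined at
  `k < 2`; such nodes are excluded from the network average by default.
  Because some ecosystems instead count them as zero, the switch
  `count_degree_lt2_as_zero` makes the convention explicit and testable.
* **Path statistics**: breadth-first distances on the simple view.
  The characteristic path length is the mean over *connected* unordered
  pairs — unreachable pairs are excluded, not counted as infinite — and
  the diameter is the maximum finite distance. This keeps both statistics
  finite on networks with stray small components, the common situation
  after a knockout. Within a single connected component the mean cannot
  exceed the maximum, so `char_path_length <= diameter` there; across
  components no such ordering is asserted.
* **Closeness centrality**: `C_c(n) = 1 / mean(L(n, m))` over the nodes
  `m` reachable from `n`; isolated nodes take 0 by convention. Values lie
  in [0, 1] and measure how quickly a signal at `n` can reach the rest of
  its component.
* **Power-law fits**: the degree spectrum (degree, count of nodes with
  that degree) and the clustering spectrum (degree, mean clustering at
  that degree, `k >= 2`) are fitted as `y = a x^b` by ordinary least
  squares of `ln y` on `ln x`, un-binned, skipping non-positive points.
  `pearson_r` is the correlation of the log-log points and
  `R² = r²`; residuals are measured on the log scale, which is the only
  scale on which the reported `r`/`R²` pair is meaningful for a
  straight-line fit. This is deliberately *not* a maximum-likelihood tail
  estimator: it is the classical network-analyzer least-squares fit, and
  a poor fit (low `R²`, e.g. for a clustering spectrum that is flat in
  `k`) is a reported result, not an error. Fewer than two usable points,
  or a degenerate (vertical) spectrum, yields `fitted = FALSE` with
  `NA` statistics.

## Compartment bridges

A node **bridges** a target set of compartments when its distinct
neighbors collectively reside in every compartment of the set: a signal
at that node is one hop from all the target districts. Two design choices
were genuinely open:

* **`include_self = FALSE` by default.** Bridging is about what a node's
  links reach, not where the node itself sits; a cytoskeletal node whose
  neighbors span the other four districts genuinely connects five
  districts only if its own is also reached by a link. The switch exists
  because the opposite reading ("the node's own district counts as
  covered") is defensible; on a single cytosol–membrane edge it flips
  both endpoints from non-bridge to bridge, which the tests pin down.
* **Default target set** = every compartment present in the network
  except `nucleus` and `extracellular`. The nucleus of a mature male germ
  cell is transcriptionally silent and molecularly stable until
  fertilization, so it is not a district that post-ejaculatory signaling
  needs to reach, and the extracellular space is not subcellular. Both
  exclusions are configurable.

A consequence worth noting: with `include_self = FALSE` a node of degree
smaller than the target-set size can never bridge, so bridges are always
reasonably connected nodes — but not necessarily the top hubs.

## Virtual knockouts and orphans

A knockout removes a node set and every incident interaction. The
**orphans** of a knockout are the nodes that belonged to the giant
(largest connected) component before the removal and lie outside the
giant component afterwards, while still being present in the network:
the knockout does not delete them, it strands them. This definition keeps
the post-knockout node count at `N - |removed|` while still speaking of
"lost" nodes, which is exactly how a detached fragment looks in a
network viewer.

Ties in giant-component size are resolved deterministically: prefer the
post-removal component sharing the most members with the pre-removal
giant, then the component whose lexicographically smallest member (C
collation) sorts first. The rule is arbitrary but fixed, which is what a
screen over all single-node knockouts needs to be reproducible; on a
two-node path split by removing the middle of three nodes, it is the
alphabetically earlier endpoint that keeps the "giant" title.

`edges_lost` counts simple-view edges, so edges internal to a removed
set count once. `knockout_screen()` ranks nodes by orphan count, then
degree, then id.

## Synthetic generators

The generators exist because real curated compartment-annotated networks
of this kind are typically not redistributable; they emulate the features
the analyses depend on, with ground truth known by construction.

* **Preferential attachment** (`generate_pa_network()`): growth from an
  `(m + 1)`-clique, each new node attaching to `m` distinct existing
  nodes with probability proportional to current degree. Defaults are
  `n = 153` nodes and `m = 1`, the size and sparsity regime
  (mean degree ≈ 2–3) of a hand-curated signaling map; compartment labels
  are drawn independently from a weight vector whose default puts most
  mass on cytosol and membrane, where most signaling species live. The
  clique seeding is pinned because alternative seeds (empty graph, star)
  change edge counts; with the clique, `E = C(m+1, 2) + m (n - m - 1)`
  exactly. The model yields connected networks with a heavy-tailed degree
  distribution — a few hubs, most nodes scarcely linked. What it does
  *not* emulate: degree–compartment correlation, modularity, or the
  curation biases of real maps, so generator-based tests demonstrate
  algorithmic correctness, not biological realism.
* **Planted-bridge networks** (`generate_planted_bridge_network()`): one
  connected module per compartment, chained by pairs of nucleus-labelled
  linker nodes (pairs, so that no linker's own neighborhood spans two
  module compartments), plus hub nodes wired into every module — the
  planted bridges — each carrying a pendant chain that its knockout
  provably orphans. Generation ends with a self-consistency gate: the
  analysis modules must recover the planted truth, or the generator
  stops.
* **The capacitation-core fixture** (`capacitation_core_fixture()`): a
  deterministic 17-node, 19-edge network encoding the documented
  neighborhood of the actin-polymerization node — eight links spanning
  five districts (phosphatidic acid, ATP, intracellular calcium, F- and
  G-actin, the two membrane-fusion events, mitochondrial protein
  translation), a PLD1/PKA backbone joining phosphatidic acid, calcium
  and ATP (PLD activation runs through the cAMP/PKA pathway), and an
  F-actin–G-actin link. Six satellite nodes are **synthetic**: invented
  here solely so that calcium and ATP each have one neighbor in
  membrane, mitochondria and acrosome, making them (with actin
  polymerization) the only five-district bridges, a property the full
  curated network has but whose supporting edges are not individually
  documented. Fixture degrees for calcium (5) and ATP (5) are therefore
  intentionally smaller than in the full map and are never asserted.

All randomness flows through `withr::with_seed`, so generators are pure
functions of their arguments and never perturb the caller's RNG state.

## Layout

`spring_embedded_layout()` implements the classical force-directed
scheme: all node pairs repel with `k² / d`, edges attract with `d² / k`,
`k = sqrt(area / n)`, displacement capped by a temperature cooling
linearly to zero from `sqrt(area) / 10`. Coordinates are a visualization
aid only: they are seed-dependent, carry no scientific content, and the
package asserts only qualitative properties (determinism for a fixed
seed, spring equilibrium near `d = k` for an isolated edge, separation of
disconnected cliques). Coincident nodes are separated by a 1e-9 distance
floor.

## Numerical conventions

* Exact statistics (distances, counts, clustering, closeness, OLS fits)
  are tested at absolute tolerance 1e-9; identity `R² = r²` at 1e-12.
* Deterministic orderings use C-collation (radix) sorting everywhere, so
  results do not depend on the session locale.
* Degenerate inputs are defined, not fatal: an edgeless network has
  diameter 0 and undefined (`NA`) path length; clustering at `k < 2` is
  `NA`; a spectrum with fewer than two usable points is `fitted = FALSE`;
  an isolated node has closeness 0 and an empty neighbor-compartment
  set.
* JSON reports fix key order, never apply locale formatting, and embed
  the schema tag `capnet-1`; serializing the same object twice is
  byte-identical.

## Test design and problem sizes

Correctness is established against independent brute-force oracles coded
separately in the test helpers (Floyd–Warshall distances, direct triangle
counting, definitional closeness, exhaustive bridge enumeration,
BFS component labeling, textbook OLS formulas) on 50 seeded random
networks of up to 30 nodes — sizes at which exhaustive checking is fast
and failures are human-readable. Scale-free generator properties
(connectedness, heavy tail, fitted exponent in [−3.5, −1], a band chosen
wide because least-squares exponents of finite preferential-attachment
networks are noisy) are checked on ten 500-node networks. These sizes
keep the full suite around ten seconds while exercising every code path;
nothing in the implementation limits networks to these sizes.

## Limitations

* Edges are unweighted, unsigned and undirected; directed or weighted
  analyses are out of scope.
* Bridging is strictly one-hop (neighborhood-based); no path-based or
  betweenness-style bottleneck scores.
* The power-law fit is descriptive least squares, not a statistical test
  of scale-freeness.
* Knockouts are structural: removing a node says nothing about dosage,
  kinetics or compensation, and orphanhood is relative to the giant
  component, not to biological function.
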