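---
title: "Classifying path types in evolving similarity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying path types in evolving similarity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(bridesnet)
```

## The question the package answers

Similarity networks — genome similarity networks in particular — are rarely
static. New genomes are sequenced and enter the network; plasmids, viruses
or eukaryotes are added to a prokaryote backbone; thresholds are relaxed and
the node set grows. The nodes that were present before ("original" nodes)
and those that arrived later ("added" nodes) then jointly determine how
information, genes or inferred relationships can travel.

For every pair of original nodes $i, j$ this package asks: *what is the
shortest simple path between $i$ and $j$ in the augmented network $Y$ that
passes through at least one added node?* Call its length the **constrained
distance** $d_c(i,j)$ ($\infty$ when no such path exists), and compare it
with the shortest-path distance $d_X(i,j)$ in the original network $X$:

| $d_X(i,j)$        | $d_c(i,j)$        | class        |
|-------------------|-------------------|--------------|
| $\infty$          | finite            | Breakthrough |
| finite            | $\infty$          | Roadblock    |
| $\infty$          | $\infty$          | Impasse      |
| $<$ $d_c$         |                   | Detour       |
| $=$ $d_c$         |                   | Equal        |
| $>$ $d_c$         |                   | Shortcut     |

The six counts over all $\binom{|N_X|}{2}$ pairs are a compact signature of
how the newcomers rewire the network: plasmids added to a prokaryote
network create Shortcuts and Breakthroughs, viruses mostly Roadblocks, and
so on. Only $N_X \subset N_Y$ is required; the augmented network may also
add or drop edges *among original nodes*, so all six classes can arise.

Paths are **simple** (loopless): allowing repeated nodes would let any walk
detour through an added node, and the quantity would be vacuous. The price
is computational: finding a shortest simple path through a prescribed set
of nodes is NP-hard in general, and even counting simple paths is #P-hard.
With a *single* must-include node the problem is polynomial, which is what
the exact reference engine exploits (below), but on large networks the
package's day-to-day classifiers are heuristics.

## The heuristic strategies

All four strategies share the same skeleton. Distances in $Y$ are computed
by Dijkstra's algorithm (nonnegative weights are required; hop counts for
unweighted input). For a pair $(i,j)$:

1. **Minimal-path screen.** Up to `max_path_number` equal-length shortest
   paths $i \leadsto j$ in $Y$ are enumerated. If one of them contains an
   added node, the constrained distance equals the unconstrained one and
   the pair is classified immediately.
2. **Candidate walk.** Otherwise a list of candidate junctions — added
   nodes $k$ reachable from both endpoints within `max_distance` — is
   ordered by $\max(d(i,k), d(j,k))$ (strategy 1, the default) or
   $d(i,k)+d(j,k)$ (strategy 2) and truncated to `max_node` entries. For
   each $k$ the strategies try to assemble a simple path $i \leadsto k
   \leadsto j$, whose length $d(i,k)+d(j,k)$ (or the rerouted length)
   becomes the witness estimate of $d_c$.
3. **Fallback.** If no witness is found the pair is a Roadblock when
   connected in $X$, an Impasse otherwise. (The fallback *must* consult
   $d_X$: a pair disconnected in both networks is an Impasse even though
   the candidate walk found nothing — the table above is the definition,
   the walk only decides existence in $Y$.)

They differ in step 2:

* `brides` pairs the stored equal-length shortest paths $i\leadsto k$ and
  $j \leadsto k$; if every pairing overlaps, it fixes one stored path,
  temporarily deletes its nodes (except $k$) from the network, reroutes
  the other endpoint by Dijkstra in the reduced network, and keeps the
  shorter of the two rerouted concatenations. The first candidate that
  yields a simple path wins.
* `brides_ec` (exhaustive concatenation) does the same but examines every
  candidate and keeps the minimum-length witness.
* `brides_y` replaces steps 1–2 entirely: it scans the `max_path_number`
  shortest loopless paths $i \leadsto j$ (Yen's algorithm) in length order
  and classifies on the first containing an added node. Within the budget
  this *is* exact — the first qualifying loopless path is the constrained
  optimum — so its only failure mode is budget exhaustion.
* `brides_yc` runs the candidate walk but concatenates pairs of
  Yen-enumerated $i\leadsto k$ and $j\leadsto k$ path lists, tried in
  nondecreasing combined length, with no rerouting.

Two properties matter for interpretation. First, every witness is a real
simple path of $Y$ through an added node, so heuristic estimates are
**upper bounds** on $d_c$: a Detour may be reported with a
longer-than-optimal length, and in unlucky configurations an Equal pair
can be misreported as a Detour. Second, `brides_y` with a small budget and
scarce added nodes misses witnesses entirely and misreports Roadblocks —
the test suite freezes minimal instances of both failure modes, and the
benchmark below quantifies the second at scale.

## Exact reference engines

`oracle_classify()` computes $d_c$ exactly, two ways:

* **Exhaustive search** (`engine = "dfs"`): branch-and-bound depth-first
  enumeration of all simple paths. Exponential; guarded by `max_nodes`
  (default 20 for the standalone function). It exists purely as an
  independent cross-check.
* **Minimum-cost flow** (`engine = "flow"`): for one must-include node
  $k$, a shortest simple $i \leadsto k \leadsto j$ path is a shortest pair
  of internally vertex-disjoint paths $k \to i$ and $k \to j$. Splitting
  every node into an in/out pair of unit capacity and sending two units of
  flow from $k$ to a super-sink attached to $i$ and $j$ (successive
  shortest augmenting paths with Johnson potentials) computes it exactly
  in polynomial time; $d_c$ is the minimum over $k$. Candidates are
  processed in increasing lower bound $d(i,k)+d(j,k)$ and the loop stops
  once the bound reaches the best exact value, so typically only one or
  two flow computations run per pair. With strictly positive weights an
  added node lying *tight* on an unconstrained shortest path
  ($d(i,k)+d(k,j) = d(i,j)$) certifies $d_c = d(i,j)$ outright, because a
  minimal-weight walk cannot contain a positive-weight cycle; this
  shortcut is disabled when any edge weight is zero.

The two engines agree on every instance both can handle; that agreement is
asserted over hundreds of seeded random instances in the test suite.

## Parameters

* `max_path_number` (default 100) — cap on stored equal-length shortest
  paths per pair, and the Yen budget. Dimensionless count.
* `max_distance` (default 100) — maximum distance from either endpoint to
  a candidate junction. In unweighted networks this bounds hop counts and
  the default is effectively inactive for networks of moderate diameter;
  in weighted networks it is in weight units and should be set
  deliberately.
* `max_node` (default 100) — cap on the candidate-list length.
* `ordering_strategy` (default 1) — the max-distance key; it tends to
  prefer junctions balanced between the endpoints.
* `length_tolerance` (default `1e-9`, relative) — all length comparisons,
  including the Equal/Detour/Shortcut boundary and the tightness test in
  shortest-path enumeration, use this relative tolerance. For unweighted
  input all lengths are small integers and comparisons are effectively
  exact.

## Numerical and design choices

* **Deterministic enumeration.** Equal-length shortest paths are
  enumerated by depth-first traversal of the tight-predecessor DAG with
  neighbours in sorted node-name order; candidate ties are broken by the
  other strategy's key, then node name; Yen concatenation pairs are tried
  in nondecreasing combined length, ties by list rank. Identical inputs
  give byte-identical outputs.
* **Zero-weight edges.** The tight-predecessor relation can be cyclic
  when edges of weight 0 exist; the enumeration keeps an on-path mask so
  returned paths stay simple regardless.
* **Reroute contract.** When stored paths overlap, the rerouting step
  deletes *all* nodes of the fixed path except the junction, not merely
  the overlapping ones. Deleting only shared nodes could introduce new
  overlaps and an unspecified iteration; the stronger contract terminates
  in one pass and guarantees the concatenation is simple, at the cost of
  occasionally missing a witness a weaker deletion would find (the
  exhaustive engines quantify how rare this is).
* **Minimal-length path sets.** The stored per-pair path lists contain
  strictly minimal-length paths only; near-minimal alternatives enter
  only through the Yen-based strategies. Equal-length alternatives beyond
  the cap are invisible to the screen in step 1 — faithful to the cap
  rather than to completeness.
* **Classification length.** When step 1 classifies a pair, the length
  used is that of the witness found (the unconstrained shortest length);
  when step 2 classifies, it is the concatenation length.
* **Disconnected pairs** in $Y$ skip the candidate walk: every candidate
  would be unreachable, so the fallback applies directly.

## The random-graph benchmark

`generate_pair()` draws the augmented network $Y$ at full size under one
of three standard models, marks a uniform random subset of nodes as added,
and induces $X$ on the rest. Generating at full size and inducing down is
model-agnostic (growing a Watts–Strogatz lattice node-by-node is not well
defined) and reproduces the structure of a growing similarity network:
every original node and edge persists in $Y$.

Model defaults are this package's choice of "sparse but connected enough
to be interesting", mean degree near 4 in all three models: Erdős–Rényi
with $p = 4/(n-1)$, Barabási–Albert preferential attachment with $m = 2$,
Watts–Strogatz with two ring neighbours per side and rewiring probability
0.05. All are overridable via `model_params`. Defaults for the experiment
grid follow the benchmark design: original networks of 100 nodes; 5, 25,
50 or 100 added nodes; 100 sampled pairs per network; `run_experiment()`
replicates default to 1000, and callers scale down.

All randomness flows from one root seed through a counter-based scheme
(seed, replicate, purpose), so any single replicate is reproducible in
isolation and runs are independent of the caller's RNG state.

What the generator does *not* emulate: weighted similarity edges, the
heavy-tailed degree and community structure of real genome networks, or
added nodes that attach preferentially to one clade. A perfect score on
this benchmark therefore shows correctness of the path machinery under
generic sparse topologies, not that heuristic witnesses are tight on any
particular empirical network — for that, run `oracle_classify()` on the
network in question.

## Scales used by the shipped checks

The automated checks run on one CPU and choose sizes accordingly: the
exact-agreement check uses 200 seeded instances with 8–15 original and 2–6
added nodes (small enough for the exhaustive engine); the full-accuracy
check uses 51 networks of 100 original + 100 added nodes with 100 sampled
pairs each; the accuracy-versus-added-nodes grid uses 12 replicates per
(model, added-count) cell at 100 original nodes and 50 sampled pairs. The
acceptance script rebuilds the 100+100 setting with 50 replicates per
model. A Monte-Carlo allowance of one percentage point is applied to the
monotonicity comparison at these replicate counts.

## A worked example

```{r example}
x <- read_edge_list(system.file("extdata", "example_x.tsv",
                                package = "bridesnet"))
y <- read_edge_list(system.file("extdata", "example_y.tsv",
                                package = "bridesnet"))
ap <- augmented_pair(x, y)
ap

res <- brides(ap)
res
subset(as.data.frame(res), is.finite(d_y_constrained))
```

The three added nodes create one pair of every kind: node 9 shortens the
1–4 route (Shortcut), node 11 duplicates the 1–3 distance (Equal) and
forces longer constrained routes for the four chain pairs (Detours), node
10 bridges the two isolated nodes (Breakthrough); the 5–6 component
contains no added node (Roadblock) and all cross-component pairs stay
Impasses.

```{r oracle}
oracle_classify(ap, engine = "flow")
```

## Known limitations

* Undirected networks with nonnegative weights only; no directed variant
  and no negative weights.
* Heuristic witness lengths are upper bounds; Detour/Equal/Shortcut
  boundaries can shift relative to the exact classification on adversarial
  weighted instances.
* The exhaustive engine is exponential and guarded; use the flow engine
  beyond toy sizes.
* `max_distance` is expressed in weight units and needs thought on
  weighted networks.
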