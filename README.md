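# bridesnet

Path-type classification in evolving similarity networks.

## The problem

Similarity networks grow: new genomes join a genome similarity network,
new proteins an interactome, new taxa an ecological co-occurrence graph.
Given the original network *X* = (N_X, E_X) and an augmented network
*Y* = (N_Y, E_Y) with N_X ⊂ N_Y, the nodes in N_Y \ N_X are the **added
nodes**. For every pair of original nodes (i, j), compare

* d_X(i, j) — the shortest-path distance in *X*, and
* d_c(i, j) — the length of the shortest **simple** path between i and j
  in *Y* that traverses **at least one added node** (∞ if none exists),

and classify the pair:

| d_X      | d_c      | class        |
|----------|----------|--------------|
| ∞        | finite   | Breakthrough |
| finite   | ∞        | Roadblock    |
| ∞        | ∞        | Impasse      |
| < d_c    |          | Detour       |
| = d_c    |          | Equal        |
| > d_c    |          | Shortcut     |

The six counts (B, R, I, D, E, S) summarize how the added nodes rewire
routes among the original nodes — e.g. whether added plasmids act as
shortcuts between distant prokaryote genomes or added viruses merely dead-end.

Because paths must be simple, computing d_c exactly is hard in general;
the package implements four heuristic strategies (`brides`, `brides_ec`,
`brides_y`, `brides_yc` — stored-path concatenation with rerouting, its
exhaustive variant, and two based on Yen's k-shortest loopless paths) and
two **exact** reference classifiers (brute-force DFS and a polynomial
minimum-cost-flow formulation) used as ground truth. A random-graph
benchmark (Erdős–Rényi, Barabási–Albert, Watts–Strogatz) scores the
heuristics against the exact reference. See the vignette
`vignettes/path-types.Rmd` for the algorithms and design choices.

For whom: anyone comparing two snapshots of an undirected (optionally
weighted) network that share a node subset — computational biologists
working with genome/gene similarity networks in particular.

## A worked example

The shipped example pair has 8 original nodes (two chains, two isolated
nodes) and 3 added nodes:

```r
library(bridesnet)
x <- read_edge_list(system.file("extdata", "example_x.tsv", package = "bridesnet"))
y <- read_edge_list(system.file("extdata", "example_y.tsv", package = "bridesnet"))
ap <- augmented_pair(x, y)
res <- brides(ap)          # default: the original first-hit strategy
res
#> Path-type classification (brides)
#>   8 original node(s), 3 added node(s), 28 pair(s)
#>   B=1 R=1 I=20 D=4 E=1 S=1
```

One pair of each kind, among the 28: added node 9 shortens the 1–4 route
from 3 to 2 (Shortcut), node 11 matches the 1–3 distance (Equal), node 10
connects the two previously isolated nodes 7 and 8 (Breakthrough); the
5–6 component contains no added node (Roadblock), and the 20 pairs
spanning different components stay Impasses. The per-pair table carries
the witness paths:

```r
subset(as.data.frame(res), is.finite(d_y_constrained))
#>    i j d_x d_y_constrained        label    witness
#> 1  1 2   1               3       Detour   1,11,3,2
#> 2  1 3   2               2        Equal     1,11,3
#> 3  1 4   3               2     Shortcut      1,9,4
#> 8  2 3   1               3       Detour   2,1,11,3
#> 9  2 4   2               3       Detour    2,1,9,4
#> 14 3 4   1               4       Detour 3,11,1,9,4
#> 28 7 8 Inf               2 Breakthrough     7,10,8
```

`oracle_classify(ap, engine = "flow")` recomputes the same table with the
exact constrained distances, and on this example agrees everywhere.

The same runs from a shell:

```sh
./exec/brides run inst/extdata/example_x.tsv inst/extdata/example_y.tsv
# B=1 R=1 I=20 D=4 E=1 S=1
./exec/brides stats inst/extdata/example_y.tsv
./exec/brides simulate --models er --n-original 30 --n-added 10 \
    --replicates 5 --pairs 50 --seed 1
```

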