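# Shared fixtures and independent brute-force oracles for the test suite.

# The 11-node example pair shipped with the package: two chains plus two
# isolated nodes, augmented by three nodes (9, 10, 11) that create one
# witness path of every kind. Exhaustively checkable by hand / DFS.
f1_x <- function() {
  read_edge_list(system.file("extdata", "example_x.tsv", package = "bridesnet"))
}
f1_y <- function() {
  read_edge_list(system.file("extdata", "example_y.tsv", package = "bridesnet"))
}
f1_pair <- function() augmented_pair(f1_x(), f1_y())

# Ground-truth six-way counts for the fixture (exhaustive enumeration of
# all simple paths of the 11-node augmented network).
f1_counts <- c(Breakthrough = 1L, Roadblock = 1L, Impasse = 20L,
               Detour = 4L, Equal = 1L, Shortcut = 1L)

# Random named (optionally weighted) G(n, p) graph for property tests.
rand_graph <- function(n, p, seed, weighted = FALSE) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  igraph::E(g)$weight <- if (weighted) {
    round(stats::runif(igraph::ecount(g), 0.5, 3), 2)
  } else {
    rep(1, igraph::ecount(g))
  }
  g
}

# Random original/augmented pair built directly (independent of
# generate_pair) for oracle and classification property tests.
rand_pair <- function(n_orig, n_add, p, seed, weighted = FALSE) {
  g <- rand_graph(n_orig + n_add, p, seed, weighted)
  nm <- igraph::V(g)$name
  set.seed(seed + 7919)
  added <- sample(nm, n_add)
  x <- igraph::induced_subgraph(g, setdiff(nm, added))
  suppressWarnings(augmented_pair(x, g))
}

# Brute-force enumeration of all simple paths between two nodes, with
# lengths: the independent oracle for the shortest-path primitives.
all_simple_paths_bf <- function(g, from, to) {
  nm <- igraph::V(g)$name
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  wmat <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  i <- match(from, nm); j <- match(to, nm)
  paths <- list(); lens <- numeric(0)
  visited <- logical(length(nm))
  stack <- integer(0)
  recurse <- function(v, len) {
    stack <<- c(stack, v); visited[v] <<- TRUE
    if (v == j) {
      paths[[length(paths) + 1L]] <<- nm[stack]
      lens <<- c(lens, len)
    } else {
      for (u in adj[[v]]) {
        if (!visited[u]) recurse(u, len + wmat[v, u])
      }
    }
    visited[v] <<- FALSE; stack <<- stack[-length(stack)]
  }
  recurse(i, 0)
  list(paths = paths, lengths = lens)
}

# Min-plus matrix closure: independent all-pairs shortest-path oracle.
minplus_closure <- function(g) {
  nm <- igraph::V(g)$name
  n <- length(nm)
  D <- matrix(Inf, n, n, dimnames = list(nm, nm))
  diag(D) <- 0
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  for (e in seq_len(nrow(el))) {
    D[el[e, 1L], el[e, 2L]] <- min(D[el[e, 1L], el[e, 2L]], w[e])
    D[el[e, 2L], el[e, 1L]] <- min(D[el[e, 2L], el[e, 1L]], w[e])
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# Constrained distance straight from the brute-force path list.
bf_constrained_distance <- function(g, from, to, added) {
  bf <- all_simple_paths_bf(g, from, to)
  keep <- vapply(bf$paths, function(p) any(p %in% added), logical(1))
  if (!any(keep)) Inf else min(bf$lengths[keep])
}
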