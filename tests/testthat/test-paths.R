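test_that("Dijkstra distances match min-plus closure on random graphs", {
  for (seed in 1:8) {
    g <- rand_graph(12, 0.3, seed, weighted = seed %% 2 == 0)
    D <- minplus_closure(g)
    for (src in igraph::V(g)$name[c(1, 5, 12)]) {
      d <- dijkstra_sssp(g, src)$dist
      expect_equal(d[colnames(D)], D[src, ], tolerance = 1e-12)
    }
  }
})

test_that("tight predecessors support every minimal path and only those", {
  g <- read_edge_list(c("1\t2", "2\t4", "1\t3", "3\t4"))
  sp <- dijkstra_sssp(g, "1")
  expect_equal(unname(sp$dist["4"]), 2)
  expect_setequal(sp$predecessors[["4"]], c("2", "3"))
  expect_equal(sp$predecessors[["1"]], character(0))
})

test_that("shortest-path enumeration is exactly the set of minimal simple paths", {
  # 4-cycle: two equal shortest paths between opposite corners
  g <- read_edge_list(c("1\t2", "2\t4", "1\t3", "3\t4"))
  ps <- enumerate_shortest_paths(g, "1", "4", cap = 10)
  expect_length(ps$paths, 2L)
  expect_false(ps$truncated)
  expect_true(all(ps$lengths == 2))

  ps1 <- enumerate_shortest_paths(g, "1", "4", cap = 1)
  expect_length(ps1$paths, 1L)
  expect_true(ps1$truncated)

  g2 <- read_edge_list(c("1\t2", "3\t4"))
  ps2 <- enumerate_shortest_paths(g2, "1", "3", cap = 5)
  expect_length(ps2$paths, 0L)
  expect_false(ps2$truncated)

  # against brute-force enumeration on random graphs
  for (seed in 1:6) {
    g <- rand_graph(10, 0.35, seed, weighted = seed %% 2 == 0)
    nm <- igraph::V(g)$name
    for (pr in list(c(1, 10), c(2, 7))) {
      bf <- all_simple_paths_bf(g, nm[pr[1]], nm[pr[2]])
      if (length(bf$paths) == 0) next
      minimal <- bf$paths[abs(bf$lengths - min(bf$lengths)) < 1e-9]
      ps <- enumerate_shortest_paths(g, nm[pr[1]], nm[pr[2]], cap = 1000)
      expect_setequal(vapply(ps$paths, paste, "", collapse = ","),
                      vapply(minimal, paste, "", collapse = ","))
    }
  }
})

test_that("Yen's algorithm returns loopless paths in nondecreasing length order", {
  g <- read_edge_list(c("1\t2", "2\t4", "1\t3", "3\t4", "1\t4"))
  ps <- yen_k_shortest(g, "1", "4", k = 3)
  expect_equal(ps$lengths, c(1, 2, 2))

  # k = 1 reduces to Dijkstra
  expect_equal(ps$lengths[1], unname(dijkstra_sssp(g, "1")$dist["4"]))

  # only two loopless paths exist; asking for five returns both
  g2 <- read_edge_list(c("1\t2", "2\t3", "1\t3"))
  ps2 <- yen_k_shortest(g2, "1", "3", k = 5)
  expect_length(ps2$paths, 2L)

  for (seed in 1:5) {
    g <- rand_graph(10, 0.35, seed, weighted = TRUE)
    ps <- yen_k_shortest(g, "v01", "v09", k = 20)
    expect_true(all(diff(ps$lengths) >= -1e-12))
    keys <- vapply(ps$paths, paste, "", collapse = ",")
    expect_false(anyDuplicated(keys) > 0)
    # every path is simple and is a real path of the graph
    bf <- all_simple_paths_bf(g, "v01", "v09")
    bf_keys <- vapply(bf$paths, paste, "", collapse = ",")
    for (p in ps$paths) {
      expect_false(anyDuplicated(p) > 0)
      expect_true(paste(p, collapse = ",") %in% bf_keys)
    }
  }
})

test_that("fixture distances route through added nodes", {
  sp <- dijkstra_sssp(f1_y(), "1")
  expect_equal(unname(sp$dist["4"]), 2)  # via added node 9
})

test_that("path concatenation joins at the junction and rejects overlaps", {
  y <- f1_y()
  p <- path_concatenate(c("1", "9"), c("4", "9"), net = y)
  expect_equal(p$nodes, c("1", "9", "4"))
  expect_equal(p$length, 2)

  expect_null(path_concatenate(c("1", "2", "9"), c("4", "2", "9")))
  expect_error(path_concatenate(c("1", "9"), c("4", "3")), "junction")

  # fully disjoint except the junction always succeeds
  p2 <- path_concatenate(c("a", "b", "k"), c("c", "d", "k"))
  expect_equal(p2$nodes, c("a", "b", "k", "d", "c"))
})

test_that("rerouting never touches the fixed path except at the junction", {
  for (seed in 1:100) {
    g <- rand_graph(10, 0.35, seed)
    nm <- igraph::V(g)$name
    sp <- dijkstra_sssp(g, nm[1])
    reach <- names(sp$dist)[is.finite(sp$dist) & names(sp$dist) != nm[1]]
    if (length(reach) < 2) next
    k <- reach[length(reach)]
    # one shortest path nm[1] -> k as the fixed path
    fixed <- enumerate_shortest_paths(g, nm[1], k, cap = 1)$paths[[1]]
    from <- setdiff(nm, fixed)[1]
    if (is.na(from)) next
    r <- reroute_shortest_path(g, fixed, from)
    if (is.null(r)) next
    expect_equal(intersect(r$nodes, fixed), k)
    expect_equal(r$nodes[1], from)
    expect_equal(r$nodes[length(r$nodes)], k)
  }
})

test_that("rerouting around a disjoint fixed path equals plain Dijkstra", {
  g <- read_edge_list(c("i\tm", "m\tk", "j\tn", "n\tk"))
  r <- reroute_shortest_path(g, c("i", "m", "k"), "j")
  expect_equal(r$nodes, c("j", "n", "k"))
  expect_equal(r$length, unname(dijkstra_sssp(g, "j")$dist["k"]))
  # unreachable after deletion
  g2 <- read_edge_list(c("i\tm", "m\tk", "j\tm"))
  expect_null(reroute_shortest_path(g2, c("i", "m", "k"), "j"))
})
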