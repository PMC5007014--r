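test_that("the six-way outcome mapping follows the distance comparison", {
  expect_equal(classify_statuses(Inf, 2), "Breakthrough")
  expect_equal(classify_statuses(2, Inf), "Roadblock")
  expect_equal(classify_statuses(Inf, Inf), "Impasse")
  expect_equal(classify_statuses(2, 3), "Detour")
  expect_equal(classify_statuses(3, 2), "Shortcut")
  expect_equal(classify_statuses(2, 2), "Equal")
  # vectorized, with tolerance on near-equal weighted lengths
  expect_equal(classify_statuses(c(1, 1 + 1e-12), c(2, 1)),
               c("Detour", "Equal"))
})

test_that("candidate lists are filtered, ordered and truncated as configured", {
  ap <- f1_pair()
  di <- dijkstra_sssp(ap$y, "1")$dist
  dj <- dijkstra_sssp(ap$y, "4")$dist

  cl <- build_candidate_list("1", "4", ap$added, di, dj)
  expect_equal(cl$k, c("9", "11"))  # 10 unreachable from both endpoints
  expect_equal(cl$d_ik, c(1, 1))
  expect_equal(cl$d_jk, c(1, 2))

  cl1 <- build_candidate_list("1", "4", ap$added, di, dj,
                              brides_params(max_node = 1))
  expect_equal(cl1$k, "9")

  cl2 <- build_candidate_list("1", "4", ap$added, di, dj,
                              brides_params(max_distance = 1))
  expect_equal(cl2$k, "9")  # 11 excluded: d(11, 4) = 2
})

test_that("all four strategies recover the fixture ground truth", {
  ap <- f1_pair()
  for (s in c("brides", "brides_ec", "brides_y", "brides_yc")) {
    res <- brides(ap, strategy = s)
    expect_equal(res$counts, f1_counts, info = s)
    expect_equal(sum(res$counts), 28L)
    # witnesses are simple, lie in Y, and contain an added node
    for (r in which(is.finite(res$records$d_y_constrained))) {
      p <- strsplit(res$records$witness[r], ",", fixed = TRUE)[[1]]
      expect_false(anyDuplicated(p) > 0)
      expect_true(any(p %in% ap$added))
      expect_equal(path_length(ap$y, p), res$records$d_y_constrained[r])
    }
  }
})

test_that("fixture per-pair labels match the exhaustive reference", {
  ap <- f1_pair()
  res <- brides(ap)
  rec <- res$records
  lab <- function(i, j) rec$label[rec$i == i & rec$j == j]
  expect_equal(lab("1", "4"), "Shortcut")
  expect_equal(lab("1", "3"), "Equal")
  expect_equal(lab("7", "8"), "Breakthrough")
  expect_equal(lab("5", "6"), "Roadblock")
  expect_equal(sort(c(lab("1", "2"), lab("2", "3"), lab("2", "4"),
                      lab("3", "4"))), rep("Detour", 4))
})

test_that("with no added nodes every pair is a Roadblock or an Impasse", {
  x <- f1_x()
  ap <- suppressWarnings(augmented_pair(x, x))
  for (s in c("brides", "brides_y", "brides_yc", "brides_ec")) {
    res <- brides(ap, strategy = s)
    expect_equal(unname(res$counts[c("Breakthrough", "Detour", "Equal",
                                     "Shortcut")]), c(0L, 0L, 0L, 0L))
    # connected-in-X pairs are Roadblocks, the rest Impasses
    dx <- igraph::distances(x)
    conn <- sum(is.finite(dx[upper.tri(dx)]))
    expect_equal(unname(res$counts["Roadblock"]), conn)
  }
})

test_that("a pair connected only through an added node is a Breakthrough", {
  x <- read_edge_list(c("2", "12"))
  y <- read_edge_list(c("2\t15", "15\t12"))
  res <- brides(x, y)
  expect_equal(res$records$label, "Breakthrough")
  expect_equal(res$records$d_y_constrained, 2)
})

test_that("a truncated Yen scan misses far-away detours", {
  # shortest path in Y avoids the added node; with a path budget of 1 the
  # Yen scan sees only that path and falls through to Roadblock, while the
  # exhaustive reference identifies the Detour
  x <- read_edge_list("i\tj")
  y <- read_edge_list(c("i\tj", "i\tk", "k\tj"))  # k added
  ap <- augmented_pair(x, y)
  res1 <- brides(ap, strategy = "brides_y",
                 params = brides_params(max_path_number = 1))
  expect_equal(res1$records$label, "Roadblock")
  orc <- oracle_classify(ap, engine = "dfs")
  expect_equal(orc$records$label, "Detour")
  expect_equal(bf_constrained_distance(ap$y, "i", "j", "k"), 2)
  # with the default budget the scan reaches the detour
  res100 <- brides(ap, strategy = "brides_y")
  expect_equal(res100$records$label, "Detour")
})

test_that("Yen-based concatenation can rescue pairs the single-path walk loses", {
  # frozen instance found by randomized search and verified by the
  # exhaustive reference: with a path budget of 1 the stored-path
  # concatenation (and its reroutes) fails for pair (o3, o6), while the
  # Yen-list concatenation finds the witness
  y <- read_edge_list(c("o1\to2", "o2\to3", "o2\to4", "o3\to4", "o1\to5",
                        "o2\to5", "o3\to5", "o3\to6", "o5\to6",
                        "o2\ta1", "o4\ta1"))
  x <- read_edge_list(c("o1\to2", "o2\to3", "o2\to4", "o3\to4", "o1\to5",
                        "o2\to5", "o3\to5", "o3\to6", "o5\to6"))
  ap <- augmented_pair(x, y)
  pair <- matrix(c("o3", "o6"), ncol = 2)
  b1 <- brides(ap, strategy = "brides",
               params = brides_params(max_path_number = 1), pairs = pair)
  yc <- brides(ap, strategy = "brides_yc", pairs = pair)
  orc <- oracle_classify(ap, engine = "dfs", pairs = pair)
  expect_equal(b1$records$label, "Roadblock")
  expect_equal(yc$records$label, "Detour")
  expect_equal(orc$records$label, "Detour")
  expect_equal(yc$records$d_y_constrained,
               bf_constrained_distance(ap$y, "o3", "o6", "a1"))
})

test_that("exhaustive concatenation finds shorter witnesses than first-hit", {
  # weighted construction: candidate k1 sorts first (smaller max-distance
  # key) and yields a witness of length 5; the later candidate k2 yields
  # length 3; with d_X = 4 the first-hit walk reports a Detour while the
  # exhaustive walk and the reference report a Shortcut
  x <- read_edge_list(c("i\tj\t4", "o"), weighted = TRUE)
  y <- read_edge_list(c("i\tk1\t2.4", "j\tk1\t2.6", "i\tk2\t2.9",
                        "j\tk2\t0.1", "i\to\t1.4", "o\tj\t1.5"),
                      weighted = TRUE)
  # the direct i-j edge of X is deliberately absent from Y
  ap <- suppressWarnings(augmented_pair(x, y))
  pair <- matrix(c("i", "j"), ncol = 2)
  b <- brides(ap, strategy = "brides", pairs = pair)
  ec <- brides(ap, strategy = "brides_ec", pairs = pair)
  orc <- oracle_classify(ap, engine = "dfs", pairs = pair)
  expect_equal(b$records$label, "Detour")
  expect_equal(b$records$d_y_constrained, 5)
  expect_equal(ec$records$label, "Shortcut")
  expect_equal(ec$records$d_y_constrained, 3)
  expect_equal(orc$records$label, "Shortcut")
  # the exhaustive witness is never longer than the first-hit witness
  expect_lte(ec$records$d_y_constrained, b$records$d_y_constrained)
})

test_that("witness lengths are upper bounds on the exact constrained distance", {
  for (seed in 1:10) {
    ap <- rand_pair(8, 3, 0.3, seed, weighted = seed %% 2 == 0)
    orc <- oracle_classify(ap, engine = "flow")
    for (s in c("brides", "brides_ec", "brides_yc")) {
      res <- brides(ap, strategy = s)
      expect_true(all(res$records$d_y_constrained >=
                        orc$records$d_y_constrained - 1e-9), info = s)
    }
    # exhaustive witnesses never exceed first-hit witnesses
    b <- brides(ap, strategy = "brides")$records$d_y_constrained
    ec <- brides(ap, strategy = "brides_ec")$records$d_y_constrained
    expect_true(all(ec <= b + 1e-9))
  }
})

test_that("relabeling nodes permutes records but leaves counts unchanged", {
  ap <- rand_pair(8, 3, 0.35, 11)
  res <- brides(ap)
  perm <- function(g) {
    nm <- igraph::V(g)$name
    igraph::set_vertex_attr(g, "name",
                            value = chartr("0123456789", "9876543210", nm))
  }
  ap2 <- suppressWarnings(augmented_pair(perm(ap$x), perm(ap$y)))
  res2 <- brides(ap2)
  expect_equal(res2$counts, res$counts)
})

test_that("counts always sum to the number of unordered original pairs", {
  for (seed in 1:4) {
    ap <- rand_pair(9, 3, 0.3, seed + 100)
    for (s in c("brides", "brides_y", "brides_yc", "brides_ec")) {
      expect_equal(sum(brides(ap, strategy = s)$counts), choose(9, 2))
    }
  }
})
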