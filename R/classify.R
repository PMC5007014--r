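# Six-way path-type classification of original node pairs in an evolving
# network, and the four heuristic strategies that estimate the constrained
# distance (shortest simple path in the augmented network forced through at
# least one added node).

PATH_CLASSES <- c("Breakthrough", "Roadblock", "Impasse",
                  "Detour", "Equal", "Shortcut")

#' Map a pair of distances to a path class
#'
#' The six-way outcome for a pair of original nodes compares the
#' shortest-path status in the original network (`d_x`) with the status of
#' the constrained path in the augmented network (`d_y`, the length of the
#' shortest simple path forced through at least one added node; `Inf` when
#' no such path exists):
#'
#' * impossible in X, possible in Y — **Breakthrough**
#' * possible in X, impossible in Y — **Roadblock**
#' * impossible in both — **Impasse**
#' * `d_x < d_y` — **Detour**
#' * equal within tolerance — **Equal**
#' * `d_x > d_y` — **Shortcut**
#'
#' @param d_x,d_y Nonnegative distances or `Inf`; vectorized.
#' @param tol Relative tolerance for the equality test (exact comparison
#'   effectively results for unweighted, integer-length input).
#' @return Character vector of class labels.
#' @examples
#' classify_statuses(Inf, 2)   # Breakthrough
#' classify_statuses(2, 3)     # Detour
#' classify_statuses(Inf, Inf) # Impasse
#' @export
classify_statuses <- function(d_x, d_y, tol = 1e-9) {
  n <- max(length(d_x), length(d_y))
  d_x <- rep_len(d_x, n)
  d_y <- rep_len(d_y, n)
  out <- character(n)
  fx <- is.finite(d_x)
  fy <- is.finite(d_y)
  out[!fx & !fy] <- "Impasse"
  out[!fx & fy] <- "Breakthrough"
  out[fx & !fy] <- "Roadblock"
  both <- fx & fy
  if (any(both)) {
    eq <- abs(d_x - d_y) <= tol * pmax(1, abs(d_x), abs(d_y))
    out[both & eq] <- "Equal"
    out[both & !eq & d_x < d_y] <- "Detour"
    out[both & !eq & d_x > d_y] <- "Shortcut"
  }
  out
}

#' Algorithm parameters
#'
#' Container for the tunable parameters of the classification heuristics.
#' `max_path_number` caps how many equal-length shortest paths (or Yen
#' paths) are stored per node pair; `max_distance` is the maximum allowed
#' distance from either endpoint to an added node for it to enter the
#' candidate list (an upper bound on hop counts in unweighted networks — it
#' should be set explicitly for weighted input); `max_node` caps the length
#' of the candidate list. All three default to 100. `ordering_strategy`
#' selects the candidate ordering key: 1 orders added nodes k by
#' `max(d(i,k), d(j,k))`, 2 by `d(i,k) + d(j,k)`.
#'
#' @param max_path_number Positive integer, default 100.
#' @param max_distance Positive number, default 100.
#' @param max_node Positive integer, default 100.
#' @param ordering_strategy 1 or 2.
#' @param length_tolerance Relative tolerance for length comparisons.
#' @return An object of class `brides_params`.
#' @export
brides_params <- function(max_path_number = 100, max_distance = 100,
                          max_node = 100, ordering_strategy = 1,
                          length_tolerance = 1e-9) {
  stopifnot(max_path_number >= 1, max_distance > 0, max_node >= 1,
            ordering_strategy %in% c(1, 2), length_tolerance >= 0)
  structure(list(max_path_number = as.integer(max_path_number),
                 max_distance = as.numeric(max_distance),
                 max_node = as.integer(max_node),
                 ordering_strategy = as.integer(ordering_strategy),
                 length_tolerance = length_tolerance),
            class = "brides_params")
}

#' @export
print.brides_params <- function(x, ...) {
  cat(sprintf(paste0("Classification parameters: MaxPathNumber=%d, ",
                     "MaxDistance=%g, MaxNode=%d, ordering strategy %d\n"),
              x$max_path_number, x$max_distance, x$max_node,
              x$ordering_strategy))
  invisible(x)
}

#' Ordered candidate list of added nodes for one pair
#'
#' Builds the list of added nodes considered as junction candidates for a
#' pair of original nodes: added nodes reachable from both endpoints within
#' `max_distance`, ordered by the active strategy key (ascending), truncated
#' to `max_node`. Ties are broken by the other strategy's key, then by node
#' name, so the order is total and reproducible.
#'
#' @param i,j Original node names.
#' @param added Character vector of added node names.
#' @param dist_i,dist_j Named distance vectors from `i` and `j` over the
#'   augmented network (e.g. `dijkstra_sssp()$dist`).
#' @param params A [brides_params()] object.
#' @return A data frame with columns `k`, `d_ik`, `d_jk`, sorted.
#' @export
build_candidate_list <- function(i, j, added, dist_i, dist_j,
                                 params = brides_params()) {
  d_ik <- dist_i[added]
  d_jk <- dist_j[added]
  keep <- is.finite(d_ik) & is.finite(d_jk) &
    d_ik <= params$max_distance & d_jk <= params$max_distance
  added <- added[keep]
  d_ik <- unname(d_ik[keep])
  d_jk <- unname(d_jk[keep])
  key1 <- pmax(d_ik, d_jk)
  key2 <- d_ik + d_jk
  o <- if (params$ordering_strategy == 1L) {
    order(key1, key2, added)
  } else {
    order(key2, key1, added)
  }
  o <- utils::head(o, params$max_node)
  data.frame(k = added[o], d_ik = d_ik[o], d_jk = d_jk[o],
             stringsAsFactors = FALSE)
}

# Index-space candidate list used by the engines. dYi/dYj are distance
# vectors over Y in vertex order; added_idx the added-node indices.
# Returns added-node indices in strategy order.
candidate_order <- function(added_idx, dYi, dYj, ranks, params) {
  d_ik <- dYi[added_idx]
  d_jk <- dYj[added_idx]
  keep <- is.finite(d_ik) & is.finite(d_jk) &
    d_ik <= params$max_distance & d_jk <= params$max_distance
  ks <- added_idx[keep]
  if (length(ks) == 0L) return(integer(0))
  d_ik <- d_ik[keep]
  d_jk <- d_jk[keep]
  key1 <- pmax(d_ik, d_jk)
  key2 <- d_ik + d_jk
  o <- if (params$ordering_strategy == 1L) {
    order(key1, key2, ranks[ks])
  } else {
    order(key2, key1, ranks[ks])
  }
  utils::head(ks[o], params$max_node)
}

#' Classify every pair of original nodes in an evolving network
#'
#' For each unordered pair of original nodes, estimates the length of the
#' shortest simple path in the augmented network that traverses at least one
#' added node, compares it with the shortest-path distance in the original
#' network, and assigns one of the six path classes (see
#' [classify_statuses()]). Four heuristic strategies are available:
#'
#' * `"brides"` — the original strategy. If some minimal-length shortest
#'   path between the pair in the augmented network already contains an
#'   added node (at most `max_path_number` equal-length shortest paths are
#'   inspected), classify directly. Otherwise walk the ordered candidate
#'   list of added nodes k and try to concatenate stored shortest paths
#'   i->k and j->k into a simple path; when the stored paths overlap, fix
#'   one of them, temporarily delete its nodes from the network, and
#'   reroute the other endpoint around it, keeping the shorter of the two
#'   rerouted concatenations. The first candidate that yields a simple
#'   path provides the witness.
#' * `"brides_ec"` — exhaustive concatenation: as `"brides"`, but all
#'   candidates k are examined and the minimum-length witness is kept.
#' * `"brides_y"` — scan the `max_path_number` shortest loopless paths
#'   between the pair (Yen's algorithm) in length order and classify using
#'   the first that contains an added node.
#' * `"brides_yc"` — as `"brides"`, but step 4 concatenates pairs of
#'   Yen-enumerated i->k and j->k paths (tried in nondecreasing combined
#'   length), with no rerouting step.
#'
#' When no witness is found, the pair is a Roadblock (connected in the
#' original network) or an Impasse (disconnected in both). The witness
#' length found by a heuristic is an upper bound on the exact constrained
#' distance, so a Detour may be reported with a longer-than-optimal length;
#' the exact reference classifiers in [oracle_classify()] provide ground
#' truth at the cost of more computation.
#'
#' @param x Original network (undirected igraph, or edge-list path), or an
#'   [augmented_pair()] object (in which case `y` is ignored).
#' @param y Augmented network containing every node of `x`.
#' @param strategy One of `"brides"`, `"brides_ec"`, `"brides_y"`,
#'   `"brides_yc"`.
#' @param params A [brides_params()] object.
#' @param pairs Optional two-column character matrix of original node
#'   pairs to classify (default: all unordered pairs).
#' @return An object of class `brides`: list with `records` (data frame
#'   `i`, `j`, `d_x`, `d_y_constrained`, `label`, `witness`), `counts`
#'   (named vector over the six classes), `strategy`, `params`, and the
#'   node counts. `print()`, `summary()`, `plot()` and `as.data.frame()`
#'   methods are provided.
#' @examples
#' x <- read_edge_list(c("1\t2", "2\t3"))
#' y <- read_edge_list(c("1\t2", "2\t3", "1\t9", "9\t3"))
#' brides(x, y)
#' @export
brides <- function(x, y = NULL,
                   strategy = c("brides", "brides_ec", "brides_y", "brides_yc"),
                   params = brides_params(), pairs = NULL) {
  strategy <- match.arg(strategy)
  ap <- as_augmented_pair(x, y)
  eng <- brides_engine(ap, params, strategy, pairs)
  new_brides_result(eng, strategy, params, ap,
                    all_pairs = is.null(pairs), call = match.call())
}

new_brides_result <- function(records, strategy, params, ap, all_pairs, call) {
  counts <- table(factor(records$label, levels = PATH_CLASSES))
  counts <- stats::setNames(as.integer(counts), PATH_CLASSES)
  structure(list(records = records, counts = counts, strategy = strategy,
                 params = params, n_original = igraph::vcount(ap$x),
                 n_added = length(ap$added), all_pairs = all_pairs,
                 call = call),
            class = "brides")
}

# -- the engine ---------------------------------------------------------------

# Shared precomputation + dispatch per strategy. `pairs` is NULL (all
# unordered original pairs) or a 2-column character matrix.
brides_engine <- function(ap, params, strategy, pairs = NULL) {
  yg <- ap$y
  ac <- adj_cache(yg)
  nmY <- ac$names
  orig <- sort(igraph::V(ap$x)$name)
  if (is.null(pairs)) {
    pairs <- if (length(orig) >= 2L) t(utils::combn(orig, 2L)) else
      matrix(character(0), ncol = 2L)
  } else {
    pairs <- as.matrix(pairs)
    stopifnot(ncol(pairs) == 2L, all(pairs %in% orig))
  }
  is_added <- rep(FALSE, ac$n)
  is_added[match(ap$added, nmY)] <- TRUE
  added_idx <- which(is_added)
  dY <- igraph::distances(yg)
  dX <- igraph::distances(ap$x)
  tol <- params$length_tolerance
  memo <- new.env(parent = emptyenv())

  n_pairs <- nrow(pairs)
  d_x <- numeric(n_pairs)
  d_yc <- numeric(n_pairs)
  witness <- character(n_pairs)
  for (r in seq_len(n_pairs)) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    iY <- match(i, nmY); jY <- match(j, nmY)
    d_x[r] <- dX[i, j]
    res <- switch(strategy,
      brides = pair_concat(ac, dY, iY, jY, added_idx, is_added, params,
                           memo, exhaustive = FALSE),
      brides_ec = pair_concat(ac, dY, iY, jY, added_idx, is_added, params,
                              memo, exhaustive = TRUE),
      brides_y = pair_yen(yg, ac, dY, iY, jY, is_added, params),
      brides_yc = pair_yen_concat(yg, ac, dY, iY, jY, added_idx, is_added,
                                  params, memo))
    if (is.null(res)) {
      d_yc[r] <- Inf
      witness[r] <- NA_character_
    } else {
      d_yc[r] <- res$length
      witness[r] <- paste(nmY[res$nodes], collapse = ",")
    }
  }
  data.frame(i = pairs[, 1L], j = pairs[, 2L], d_x = d_x,
             d_y_constrained = d_yc,
             label = classify_statuses(d_x, d_yc, tol),
             witness = witness, stringsAsFactors = FALSE)
}

# Memoized enumeration of minimal-length shortest paths u..v in Y
# (index space). Distances from u come from the all-pairs matrix.
memo_enum <- function(memo, ac, dY, u, v, params) {
  key <- paste0("e", u, "_", v)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  res <- ac_enumerate_shortest(ac, dY[u, ], u, v, params$max_path_number,
                               params$length_tolerance)
  memo[[key]] <- res
  res
}

# Original / exhaustive-concatenation strategies for one pair.
# Returns list(nodes = integer path, length = numeric) or NULL.
pair_concat <- function(ac, dY, iY, jY, added_idx, is_added, params, memo,
                        exhaustive) {
  # step 3: some minimal-length shortest path i..j already passes an added node
  hit <- step3_minimal_witness(ac, dY, iY, jY, is_added, params, memo)
  if (!is.null(hit)) return(hit)
  # step 4: walk the candidate list
  ks <- candidate_order(added_idx, dY[iY, ], dY[jY, ], ac$rank, params)
  best <- NULL
  for (k in ks) {
    cand <- concat_via_k(ac, dY, iY, jY, k, params, memo, reroute = TRUE)
    if (!is.null(cand)) {
      if (!exhaustive) return(cand)
      if (is.null(best) || cand$length < best$length - 1e-12) best <- cand
    }
  }
  best
}

step3_minimal_witness <- function(ac, dY, iY, jY, is_added, params, memo) {
  if (!is.finite(dY[iY, jY])) return(NULL)
  enum <- memo_enum(memo, ac, dY, iY, jY, params)
  for (p in enum$paths) {
    if (any(is_added[p])) {
      return(list(nodes = p, length = dY[iY, jY]))
    }
  }
  NULL
}

# Try to route i..k..j through candidate k using stored shortest paths
# (step 4.1: every pairing of stored i->k and j->k paths, in rank order);
# optionally fall back to the reroute step (4.2): fix one stored path,
# delete its nodes (except k), recompute the other side by Dijkstra in the
# reduced network, and keep the shorter of the two rerouted concatenations.
concat_via_k <- function(ac, dY, iY, jY, k, params, memo, reroute) {
  P_ik <- memo_enum(memo, ac, dY, iY, k, params)$paths
  P_jk <- memo_enum(memo, ac, dY, jY, k, params)$paths
  if (length(P_ik) == 0L || length(P_jk) == 0L) return(NULL)
  len41 <- dY[iY, k] + dY[jY, k]
  for (p in P_ik) {
    p_body <- p[-length(p)]
    for (q in P_jk) {
      q_body <- q[-length(q)]
      if (!any(match(p_body, q_body, nomatch = 0L) > 0L)) {
        return(list(nodes = c(p, rev(q_body)), length = len41))
      }
    }
  }
  if (!reroute) return(NULL)
  best <- NULL
  p1 <- P_ik[[1L]]
  if (!(jY %in% p1)) {
    r1 <- ac_reroute(ac, p1, jY)
    if (!is.null(r1)) {
      best <- list(nodes = c(p1, rev(r1$nodes[-length(r1$nodes)])),
                   length = dY[iY, k] + r1$length)
    }
  }
  q1 <- P_jk[[1L]]
  if (!(iY %in% q1)) {
    r2 <- ac_reroute(ac, q1, iY)
    if (!is.null(r2) &&
        (is.null(best) || dY[jY, k] + r2$length < best$length - 1e-12)) {
      best <- list(nodes = c(r2$nodes, rev(q1[-length(q1)])),
                   length = dY[jY, k] + r2$length)
    }
  }
  best
}

# Yen-scan strategy: first of the (at most max_path_number) shortest
# loopless paths i..j that contains an added node. The scan grows the Yen
# call geometrically so the common case (an early path qualifies) never
# pays for the full path budget.
pair_yen <- function(yg, ac, dY, iY, jY, is_added, params) {
  if (!is.finite(dY[iY, jY])) return(NULL)  # no loopless path at all
  maxp <- params$max_path_number
  from <- ac$names[iY]; to <- ac$names[jY]
  w <- igraph::E(yg)$weight
  ks <- unique(pmin(c(4L, 16L, 64L, maxp), maxp))
  for (K in ks) {
    res <- igraph::k_shortest_paths(yg, from = from, to = to, k = K)
    for (idx in seq_along(res$vpaths)) {
      p <- as.integer(res$vpaths[[idx]])
      if (any(is_added[p])) {
        return(list(nodes = p,
                    length = sum(w[as.integer(res$epaths[[idx]])])))
      }
    }
    if (length(res$vpaths) < K) return(NULL)  # all loopless paths exhausted
  }
  NULL
}

# Memoized Yen path list u..v (index space), with lengths.
memo_yen <- function(memo, yg, ac, u, v, params) {
  key <- paste0("y", u, "_", v)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  res <- igraph::k_shortest_paths(yg, from = ac$names[u], to = ac$names[v],
                                  k = params$max_path_number)
  w <- igraph::E(yg)$weight
  out <- list(paths = lapply(res$vpaths, as.integer),
              lengths = vapply(res$epaths,
                               function(e) sum(w[as.integer(e)]), numeric(1)))
  memo[[key]] <- out
  out
}

# Yen + concatenation strategy: step 4 pairs Yen-enumerated i->k and j->k
# paths in nondecreasing combined length (ties by list rank); the first
# simple concatenation wins; no reroute step.
pair_yen_concat <- function(yg, ac, dY, iY, jY, added_idx, is_added, params,
                            memo) {
  hit <- step3_minimal_witness(ac, dY, iY, jY, is_added, params, memo)
  if (!is.null(hit)) return(hit)
  ks <- candidate_order(added_idx, dY[iY, ], dY[jY, ], ac$rank, params)
  for (k in ks) {
    P_ik <- memo_yen(memo, yg, ac, iY, k, params)
    P_jk <- memo_yen(memo, yg, ac, jY, k, params)
    na <- length(P_ik$paths); nb <- length(P_jk$paths)
    if (na == 0L || nb == 0L) next
    tot <- outer(P_ik$lengths, P_jk$lengths, `+`)
    ia <- row(tot); ib <- col(tot)
    for (idx in order(tot, ia, ib)) {
      p <- P_ik$paths[[ia[idx]]]
      q <- P_jk$paths[[ib[idx]]]
      p_body <- p[-length(p)]
      q_body <- q[-length(q)]
      if (!any(match(p_body, q_body, nomatch = 0L) > 0L)) {
        return(list(nodes = c(p, rev(q_body)), length = tot[idx]))
      }
    }
  }
  NULL
}
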