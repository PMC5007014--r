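# Exact reference classifiers.
#
# The heuristics in classify.R report upper bounds on the constrained
# distance (shortest simple path between two original nodes forced through
# at least one added node). Two independent exact engines provide ground
# truth:
#   * a brute-force depth-first search over all simple paths (exponential,
#     guarded to small instances), and
#   * a polynomial minimum-cost-flow formulation: for a single must-include
#     node k, the constrained shortest simple path i..k..j is a shortest
#     pair of internally vertex-disjoint paths k->i and k->j, computed
#     exactly by node splitting and a two-unit minimum-cost flow; the
#     constrained distance is the minimum over added nodes k.

#' Exact constrained distance by exhaustive depth-first search
#'
#' Minimum length over *all* simple paths between two nodes that contain at
#' least one member of `added`; `Inf` when no such path exists. Runs in
#' exponential time (branch-and-bound over simple paths) and is therefore
#' guarded to small instances; it exists as an independent cross-check of
#' [flow_constrained_distance()].
#'
#' @param net Undirected igraph graph (the augmented network).
#' @param from,to Node names.
#' @param added Character vector of added node names.
#' @param max_nodes Refuse instances with more nodes than this.
#' @return Numeric distance or `Inf`.
#' @export
dfs_constrained_distance <- function(net, from, to, added, max_nodes = 20) {
  net <- as_brides_network(net)
  if (igraph::vcount(net) > max_nodes) {
    stop("instance has ", igraph::vcount(net), " nodes; the exhaustive ",
         "search is guarded to max_nodes = ", max_nodes, call. = FALSE)
  }
  ac <- adj_cache(net)
  i <- match(as.character(from), ac$names)
  j <- match(as.character(to), ac$names)
  if (is.na(i) || is.na(j)) stop("endpoint not in network", call. = FALSE)
  is_added <- rep(FALSE, ac$n)
  is_added[match(added, ac$names)] <- TRUE
  dfs_constrained_idx(ac, i, j, is_added)
}

dfs_constrained_idx <- function(ac, i, j, is_added) {
  best <- Inf
  visited <- logical(ac$n)
  descend <- function(v, len, seen) {
    if (v == j) {
      if (seen && len < best) best <<- len
      return()
    }
    visited[v] <<- TRUE
    nb <- ac$adj[[v]]
    wv <- ac$adjw[[v]]
    for (t in seq_along(nb)) {
      u <- nb[t]
      if (!visited[u]) {
        nl <- len + wv[t]
        if (nl < best) descend(u, nl, seen || is_added[u])
      }
    }
    visited[v] <<- FALSE
  }
  if (i == j) return(if (is_added[i]) 0 else Inf)
  descend(i, 0, is_added[i])
  best
}

#' Exact constrained distance by minimum-cost flow
#'
#' Polynomial-time exact computation of the constrained distance: for each
#' added node k reachable from both endpoints, the shortest simple path
#' i..k..j equals the minimum total length of two internally
#' vertex-disjoint paths k->i and k->j, obtained as a two-unit minimum-cost
#' flow on the node-split network. The result is the minimum over k, with
#' candidates processed in increasing `d(i,k) + d(j,k)` so the search can
#' stop as soon as that lower bound meets the best exact value found.
#'
#' @inheritParams dfs_constrained_distance
#' @return Numeric distance or `Inf`; agrees with
#'   [dfs_constrained_distance()] on every input.
#' @export
flow_constrained_distance <- function(net, from, to, added) {
  net <- as_brides_network(net)
  ac <- adj_cache(net)
  i <- match(as.character(from), ac$names)
  j <- match(as.character(to), ac$names)
  if (is.na(i) || is.na(j)) stop("endpoint not in network", call. = FALSE)
  added_idx <- match(intersect(added, ac$names), ac$names)
  fn <- build_flow_net(net, ac)
  di <- ac_dijkstra(ac, i)$dist
  dj <- ac_dijkstra(ac, j)$dist
  flow_constrained_idx(ac, fn, i, j, di, dj, added_idx)
}

flow_constrained_idx <- function(ac, fn, i, j, di, dj, added_idx) {
  if (length(added_idx) == 0L) return(Inf)
  lb <- di[added_idx] + dj[added_idx]
  ok <- is.finite(lb)
  ks <- added_idx[ok]
  if (length(ks) == 0L) return(Inf)
  lb <- lb[ok]
  # with strictly positive weights, a walk of total weight d(i,j) cannot
  # contain a cycle, so any added node tight on the unconstrained shortest
  # path certifies constrained distance == unconstrained distance
  dij <- min(di[j], Inf)
  if (ac$min_w > 0 && is.finite(dij) &&
      any(abs(lb - dij) <= 1e-9 * max(1, dij))) {
    return(dij)
  }
  o <- order(lb)
  ks <- ks[o]
  lb <- lb[o]
  best <- Inf
  for (t in seq_along(ks)) {
    if (lb[t] >= best - 1e-12) break
    v <- flow_two_units(fn, ks[t], i, j)
    if (v < best) best <- v
  }
  best
}

# Static part of the node-split flow network for one graph.
# Node ids: 1..n are in-copies, n+1..2n out-copies, 2n+1 the super sink.
# Forward arc t lives at index 2t-1, its residual twin at 2t.
# Forward arcs, in order: split arcs v_in->v_out (t = v, cap 1, cost 0);
# two directed arcs per undirected edge (out->in, cap 1, cost w); sink arcs
# v_out->T for every v (cap 0 until activated per query).
build_flow_net <- function(net, ac = adj_cache(net)) {
  n <- ac$n
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- igraph::E(net)$weight
  ne <- nrow(el)
  f_from <- c(seq_len(n), n + el[, 1L], n + el[, 2L], n + seq_len(n))
  f_to <- c(n + seq_len(n), el[, 2L], el[, 1L], rep(2L * n + 1L, n))
  f_cost <- c(rep(0, n), w, w, rep(0, n))
  f_cap <- c(rep(1L, n), rep(1L, 2L * ne), rep(0L, n))
  m <- length(f_from)
  a_from <- as.vector(rbind(f_from, f_to))
  a_to <- as.vector(rbind(f_to, f_from))
  a_cost <- as.vector(rbind(f_cost, -f_cost))
  a_cap <- as.vector(rbind(f_cap, rep(0L, m)))
  nn <- 2L * n + 1L
  out_arcs <- vector("list", nn)
  sp <- split(seq_len(2L * m), a_from)
  out_arcs[as.integer(names(sp))] <- sp
  list(n = n, nn = nn, a_from = a_from, a_to = a_to, a_cost = a_cost,
       cap0 = a_cap, out_arcs = out_arcs,
       split_arc = function(v) 2L * v - 1L,
       sink_arc = function(v) 2L * (n + 2L * ne + v) - 1L)
}

# Exact min total length of two internally vertex-disjoint paths k->i and
# k->j (successive shortest augmenting paths with Johnson potentials).
flow_two_units <- function(fn, k, i, j) {
  cap <- fn$cap0
  cap[fn$split_arc(k)] <- 0L        # the junction must not be re-entered
  cap[fn$sink_arc(i)] <- 1L
  cap[fn$sink_arc(j)] <- 1L
  nn <- fn$nn
  src <- fn$n + k                    # k's out-copy
  snk <- nn
  pot <- numeric(nn)
  total <- 0
  for (unit in 1:2) {
    dist <- rep(Inf, nn)
    parc <- rep(NA_integer_, nn)
    done <- logical(nn)
    dist[src] <- 0
    repeat {
      d <- dist
      d[done] <- Inf
      v <- which.min(d)
      if (!is.finite(d[v])) break
      done[v] <- TRUE
      if (v == snk) break
      for (a in fn$out_arcs[[v]]) {
        if (cap[a] > 0L) {
          u <- fn$a_to[a]
          nd <- dist[v] + fn$a_cost[a] + pot[v] - pot[u]
          if (nd < dist[u] - 1e-12) {
            dist[u] <- nd
            parc[u] <- a
          }
        }
      }
    }
    if (!is.finite(dist[snk])) return(Inf)
    fin <- is.finite(dist)
    dist[!fin] <- max(dist[fin])
    pot <- pot + dist
    v <- snk
    while (v != src) {
      a <- parc[v]
      cap[a] <- cap[a] - 1L
      twin <- if (a %% 2L == 1L) a + 1L else a - 1L
      cap[twin] <- cap[twin] + 1L
      total <- total + fn$a_cost[a]
      v <- fn$a_from[a]
    }
  }
  total
}

#' Exact reference classification of all original pairs
#'
#' Classifies every pair of original nodes using the *exact* constrained
#' distance instead of a heuristic estimate, via either the brute-force
#' depth-first engine (small instances only) or the polynomial
#' minimum-cost-flow engine. Used as ground truth when benchmarking the
#' heuristic strategies.
#'
#' @inheritParams brides
#' @param engine `"flow"` (polynomial, default) or `"dfs"` (exponential,
#'   guarded by `max_nodes`).
#' @param max_nodes Instance-size guard for the `"dfs"` engine.
#' @return A `brides` object (witness paths are not reported).
#' @export
oracle_classify <- function(x, y = NULL, engine = c("flow", "dfs"),
                            params = brides_params(), pairs = NULL,
                            max_nodes = 30) {
  engine <- match.arg(engine)
  ap <- as_augmented_pair(x, y)
  ac <- adj_cache(ap$y)
  nmY <- ac$names
  orig <- sort(igraph::V(ap$x)$name)
  if (is.null(pairs)) {
    pairs <- if (length(orig) >= 2L) t(utils::combn(orig, 2L)) else
      matrix(character(0), ncol = 2L)
  } else {
    pairs <- as.matrix(pairs)
  }
  if (engine == "dfs" && ac$n > max_nodes) {
    stop("augmented network has ", ac$n, " nodes; the dfs engine is ",
         "guarded to max_nodes = ", max_nodes, call. = FALSE)
  }
  is_added <- rep(FALSE, ac$n)
  added_idx <- match(ap$added, nmY)
  is_added[added_idx] <- TRUE
  dX <- igraph::distances(ap$x)
  dY <- igraph::distances(ap$y)
  fn <- if (engine == "flow") build_flow_net(ap$y, ac) else NULL
  n_pairs <- nrow(pairs)
  d_x <- numeric(n_pairs)
  d_c <- numeric(n_pairs)
  for (r in seq_len(n_pairs)) {
    i <- match(pairs[r, 1L], nmY)
    j <- match(pairs[r, 2L], nmY)
    d_x[r] <- dX[pairs[r, 1L], pairs[r, 2L]]
    d_c[r] <- if (engine == "dfs") {
      dfs_constrained_idx(ac, i, j, is_added)
    } else {
      flow_constrained_idx(ac, fn, i, j, dY[i, ], dY[j, ], added_idx)
    }
  }
  records <- data.frame(i = pairs[, 1L], j = pairs[, 2L], d_x = d_x,
                        d_y_constrained = d_c,
                        label = classify_statuses(d_x, d_c,
                                                  params$length_tolerance),
                        witness = NA_character_, stringsAsFactors = FALSE)
  new_brides_result(records, paste0("oracle_", engine), params, ap,
                    all_pairs = is.null(pairs), call = match.call())
}
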