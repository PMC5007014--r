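# Shortest-path primitives.
#
# Public wrappers operate on igraph graphs with named vertices; the
# classification engines use an internal index-based adjacency cache so the
# inner loops avoid repeated igraph dispatch.

# -- internal adjacency cache -------------------------------------------------

# List representation of an undirected weighted graph:
#   n          number of vertices
#   names      vertex names (igraph order)
#   rank       integer rank of each vertex in sorted-name order (tie-break
#              order for deterministic enumeration)
#   adj[[v]]   integer vector of neighbours of v
#   adjw[[v]]  matching edge weights
adj_cache <- function(net) {
  n <- igraph::vcount(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- igraph::E(net)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  adj <- rep(list(integer(0)), n)
  adjw <- rep(list(numeric(0)), n)
  if (nrow(el) > 0L) {
    ends <- c(el[, 1L], el[, 2L])
    other <- c(el[, 2L], el[, 1L])
    ww <- c(w, w)
    o <- order(ends)
    ends <- ends[o]; other <- other[o]; ww <- ww[o]
    runs <- rle(ends)
    stop_at <- cumsum(runs$lengths)
    start_at <- stop_at - runs$lengths + 1L
    for (r in seq_along(runs$values)) {
      v <- runs$values[r]
      adj[[v]] <- other[start_at[r]:stop_at[r]]
      adjw[[v]] <- ww[start_at[r]:stop_at[r]]
    }
  }
  nm <- igraph::V(net)$name
  list(n = n, names = nm, rank = match(nm, sort(nm)), adj = adj, adjw = adjw,
       min_w = if (length(w)) min(w) else Inf)
}

# Single-source Dijkstra on the adjacency cache. O(n^2) scan, adequate for
# the network sizes this package targets. `forbidden` marks vertices that
# must not be entered (the source itself is always allowed).
# Returns list(dist = numeric(n), parent = integer(n)); parent is one tight
# predecessor per vertex (NA at the source / unreachable vertices).
ac_dijkstra <- function(ac, src, forbidden = NULL) {
  n <- ac$n
  dist <- rep(Inf, n)
  parent <- rep(NA_integer_, n)
  done <- logical(n)
  if (!is.null(forbidden)) {
    done[forbidden] <- TRUE
    dist[forbidden] <- NA_real_
  }
  done[src] <- FALSE
  dist[src] <- 0
  repeat {
    d <- dist
    d[done] <- Inf
    v <- which.min(d)
    if (length(v) == 0L || !is.finite(d[v])) break
    done[v] <- TRUE
    nb <- ac$adj[[v]]
    if (length(nb)) {
      cand <- dist[v] + ac$adjw[[v]]
      ok <- !done[nb] & (is.na(dist[nb]) | cand < dist[nb])
      ok[is.na(ok)] <- FALSE
      if (any(ok)) {
        dist[nb[ok]] <- cand[ok]
        parent[nb[ok]] <- v
      }
    }
  }
  dist[is.na(dist)] <- Inf
  list(dist = dist, parent = parent)
}

# Reconstruct src..dst from the parent pointers of ac_dijkstra.
ac_walk_back <- function(parent, src, dst) {
  path <- dst
  v <- dst
  while (v != src) {
    v <- parent[v]
    if (is.na(v)) return(NULL)
    path <- c(v, path)
  }
  path
}

# Relative-tolerance test for "u is a tight predecessor of v":
# dist[u] + w == dist[v]. Exact for unit weights.
tight_ok <- function(du, w, dv, tol) {
  abs(du + w - dv) <= tol * max(1, abs(dv))
}

# Enumerate up to `cap` minimal-length simple paths src..dst as integer
# vectors, by depth-first traversal of the tight-predecessor relation from
# dst back to src, expanding predecessors in sorted-name order. The `onpath`
# guard keeps the walk simple even in the presence of zero-weight edges
# (whose tight relation may contain cycles).
# Returns list(paths = list(), truncated = flag).
ac_enumerate_shortest <- function(ac, dist, src, dst, cap, tol = 1e-9) {
  if (!is.finite(dist[dst])) {
    return(list(paths = list(), truncated = FALSE))
  }
  paths <- vector("list", cap)
  count <- 0L
  truncated <- FALSE
  onpath <- logical(ac$n)
  stack <- integer(0)

  descend <- function(v) {
    if (truncated) return()
    stack <<- c(stack, v)
    onpath[v] <<- TRUE
    if (v == src) {
      if (count == cap) {
        truncated <<- TRUE
      } else {
        count <<- count + 1L
        paths[[count]] <<- rev(stack)
      }
    } else {
      nb <- ac$adj[[v]]
      wv <- ac$adjw[[v]]
      keep <- which(!onpath[nb] &
                      abs(dist[nb] + wv - dist[v]) <= tol * max(1, abs(dist[v])))
      if (length(keep)) {
        keep <- keep[order(ac$rank[nb[keep]])]
        for (u in nb[keep]) {
          if (truncated) break
          descend(u)
        }
      }
    }
    onpath[v] <<- FALSE
    stack <<- stack[-length(stack)]
  }

  descend(dst)
  list(paths = paths[seq_len(count)], truncated = truncated)
}

# -- public wrappers ----------------------------------------------------------

#' Single-source shortest paths with all tight predecessors
#'
#' Runs Dijkstra's algorithm from `source` and, besides the distance to
#' every node, reports *every* tight predecessor of each node, i.e. every
#' neighbour `u` of `v` with `d(u) + w(u,v) = d(v)`. The tight-predecessor
#' relation is the DAG whose source-to-node paths are exactly the
#' minimal-length simple paths, which is what supports enumeration of
#' equal-length shortest paths.
#'
#' @param net Undirected igraph graph with nonnegative edge weights.
#' @param source Node name.
#' @param tol Relative tolerance for the tightness test (exact for
#'   unit-weight graphs).
#' @return A list with `dist` (named numeric vector, `Inf` when
#'   unreachable) and `predecessors` (named list of character vectors).
#' @export
dijkstra_sssp <- function(net, source, tol = 1e-9) {
  net <- as_brides_network(net)
  ac <- adj_cache(net)
  s <- match(as.character(source), ac$names)
  if (is.na(s)) stop("source node ", dQuote(source), " not in network", call. = FALSE)
  dist <- ac_dijkstra(ac, s)$dist
  preds <- lapply(seq_len(ac$n), function(v) {
    if (!is.finite(dist[v]) || v == s) return(character(0))
    nb <- ac$adj[[v]]
    keep <- abs(dist[nb] + ac$adjw[[v]] - dist[v]) <= tol * max(1, abs(dist[v]))
    sort(ac$names[nb[keep]])
  })
  names(preds) <- ac$names
  dist <- stats::setNames(dist, ac$names)
  list(dist = dist, predecessors = preds)
}

#' Enumerate equal-length shortest simple paths
#'
#' Returns up to `cap` distinct simple paths between two nodes, all of
#' exactly minimal length, by deterministic depth-first traversal of the
#' tight-predecessor DAG (neighbours expanded in sorted node-name order).
#'
#' @param net Undirected igraph graph.
#' @param from,to Node names.
#' @param cap Maximum number of paths to return (>= 1).
#' @param tol Relative tolerance for length comparisons.
#' @return A `path_set`: list with `source`, `target`, `paths` (list of
#'   character vectors), `lengths` (numeric), and `truncated` (`TRUE` iff
#'   more minimal paths exist than `cap`). Empty `paths` when the nodes are
#'   disconnected.
#' @export
enumerate_shortest_paths <- function(net, from, to, cap = 100, tol = 1e-9) {
  stopifnot(cap >= 1)
  net <- as_brides_network(net)
  ac <- adj_cache(net)
  i <- match(as.character(from), ac$names)
  j <- match(as.character(to), ac$names)
  if (is.na(i) || is.na(j)) {
    stop("node ", dQuote(if (is.na(i)) from else to), " not in network",
         call. = FALSE)
  }
  dist <- ac_dijkstra(ac, i)$dist
  enum <- ac_enumerate_shortest(ac, dist, i, j, as.integer(cap), tol)
  new_path_set(ac$names[i], ac$names[j],
               lapply(enum$paths, function(p) ac$names[p]),
               rep(dist[j], length(enum$paths)),
               enum$truncated)
}

#' Yen's k-shortest loopless paths
#'
#' The `k` shortest simple (loopless) paths between two nodes, in
#' nondecreasing length order; the first path is a shortest path. When
#' fewer than `k` loopless paths exist, all of them are returned.
#'
#' @inheritParams enumerate_shortest_paths
#' @param k Maximum number of paths (>= 1).
#' @return A `path_set` (see [enumerate_shortest_paths()]); `truncated` is
#'   `TRUE` when exactly `k` paths were returned (more may exist).
#' @export
yen_k_shortest <- function(net, from, to, k = 100) {
  stopifnot(k >= 1)
  net <- as_brides_network(net)
  from <- as.character(from)
  to <- as.character(to)
  if (!(from %in% igraph::V(net)$name) || !(to %in% igraph::V(net)$name)) {
    stop("endpoint not in network", call. = FALSE)
  }
  res <- igraph::k_shortest_paths(net, from = from, to = to, k = as.integer(k))
  w <- igraph::E(net)$weight
  lens <- vapply(res$epaths, function(e) sum(w[as.integer(e)]), numeric(1))
  new_path_set(from, to, lapply(res$vpaths, names), lens,
               truncated = length(res$vpaths) == k)
}

new_path_set <- function(source, target, paths, lengths, truncated) {
  structure(list(source = source, target = target, paths = paths,
                 lengths = as.numeric(lengths), truncated = truncated),
            class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("Path set %s -> %s: %d path(s)%s\n", x$source, x$target,
              length(x$paths), if (x$truncated) " (truncated)" else ""))
  for (idx in seq_len(min(10L, length(x$paths)))) {
    cat(sprintf("  [%g] %s\n", x$lengths[idx],
                paste(x$paths[[idx]], collapse = " - ")))
  }
  if (length(x$paths) > 10L) cat("  ...\n")
  invisible(x)
}

#' Concatenate two paths meeting at a common terminal node
#'
#' Joins a path `i -> ... -> k` with a path `j -> ... -> k` into the single
#' path `i -> ... -> k -> ... -> j`, provided the two share no node other
#' than the junction `k` (otherwise the result would not be simple and
#' `NULL` is returned). The length of the concatenation is the sum of the
#' two path lengths.
#'
#' @param p_ik,p_jk Character vectors of node names, both ending at the
#'   same junction node.
#' @param net Optional igraph graph used to compute the concatenated
#'   length from edge weights.
#' @return A list with `nodes` and (when `net` is given) `length`, or
#'   `NULL` when the concatenation is not simple.
#' @export
path_concatenate <- function(p_ik, p_jk, net = NULL) {
  k <- p_ik[length(p_ik)]
  if (p_jk[length(p_jk)] != k) {
    stop("paths do not share a terminal junction node", call. = FALSE)
  }
  a <- p_ik[-length(p_ik)]
  b <- p_jk[-length(p_jk)]
  if (length(intersect(a, b)) > 0L) return(NULL)
  nodes <- c(p_ik, rev(b))
  out <- list(nodes = nodes)
  if (!is.null(net)) out$length <- path_length(net, nodes)
  out
}

#' Length of a path given as a node sequence
#'
#' Sum of edge weights along consecutive nodes; errors when the sequence is
#' not a path of the network.
#'
#' @param net Undirected igraph graph.
#' @param nodes Character vector of node names.
#' @return Numeric length (0 for a single node).
#' @export
path_length <- function(net, nodes) {
  if (length(nodes) < 2L) return(0)
  vp <- as.vector(rbind(nodes[-length(nodes)], nodes[-1L]))
  ids <- igraph::get_edge_ids(net, vp)
  if (any(ids == 0L)) {
    stop("node sequence is not a path in the network", call. = FALSE)
  }
  sum(igraph::E(net)$weight[ids])
}

#' Reroute around a fixed path
#'
#' Deletes every node of `fixed` except its terminal node `k` from the
#' network, then computes a shortest path from `from` to `k` in the reduced
#' network. Deleting the whole fixed path (rather than only nodes actually
#' shared with some tentative path) guarantees that concatenating `fixed`
#' with the returned path always yields a simple path.
#'
#' @param net Undirected igraph graph.
#' @param fixed Character vector of node names; the fixed path, terminating
#'   at the junction node.
#' @param from Node to reroute from; must not lie on `fixed`.
#' @return A list with `nodes` (path `from -> ... -> k`) and `length`, or
#'   `NULL` when the reduced network disconnects `from` from `k`.
#' @export
reroute_shortest_path <- function(net, fixed, from) {
  net <- as_brides_network(net)
  from <- as.character(from)
  if (from %in% fixed) {
    stop("`from` must not lie on the fixed path", call. = FALSE)
  }
  ac <- adj_cache(net)
  res <- ac_reroute(ac, match(fixed, ac$names), match(from, ac$names))
  if (is.null(res)) return(NULL)
  list(nodes = ac$names[res$nodes], length = res$length)
}

# Index-based reroute: shortest from -> k in the graph minus fixed[-last].
ac_reroute <- function(ac, fixed_idx, from_idx) {
  k <- fixed_idx[length(fixed_idx)]
  forb <- fixed_idx[-length(fixed_idx)]
  dj <- ac_dijkstra(ac, from_idx, forbidden = forb)
  if (!is.finite(dj$dist[k])) return(NULL)
  list(nodes = ac_walk_back(dj$parent, from_idx, k), length = dj$dist[k])
}
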