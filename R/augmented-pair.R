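#' Bundle an original network with its augmented version
#'
#' Validates that every node of the original network `x` is present in the
#' augmented network `y` and records the set of *added* nodes (nodes of `y`
#' absent from `x`). The edge sets are deliberately unconstrained: the
#' augmented network may rewire, add or drop edges among the original nodes.
#'
#' A warning (not an error) is emitted when no node was added, or when some
#' edge of `x` is missing from `y` — both are legitimate but often indicate
#' the two files were swapped.
#'
#' @param x Original network: an undirected igraph graph or an edge-list
#'   file path (see [read_edge_list()]).
#' @param y Augmented network, same forms accepted.
#' @return An object of class `augmented_pair`: a list with elements
#'   `x`, `y` (igraph graphs) and `added` (character vector of added node
#'   names, sorted).
#' @examples
#' x <- read_edge_list(c("1\t2", "3"))
#' y <- read_edge_list(c("1\t2", "2\t9", "9\t3"))
#' ap <- augmented_pair(x, y)
#' ap$added
#' @export
augmented_pair <- function(x, y) {
  x <- as_brides_network(x, "x")
  y <- as_brides_network(y, "y")
  nx <- igraph::V(x)$name
  ny <- igraph::V(y)$name
  missing <- setdiff(nx, ny)
  if (length(missing) > 0L) {
    stop("original nodes absent from the augmented network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  added <- sort(setdiff(ny, nx))
  if (length(added) == 0L) {
    warning("no added nodes: the augmented network has the same node set ",
            "as the original", call. = FALSE)
  }
  ex <- igraph::as_edgelist(x)
  if (nrow(ex) > 0L) {
    key_x <- paste(pmin(ex[, 1L], ex[, 2L]), pmax(ex[, 1L], ex[, 2L]))
    ey <- igraph::as_edgelist(y)
    key_y <- if (nrow(ey) > 0L) {
      paste(pmin(ey[, 1L], ey[, 2L]), pmax(ey[, 1L], ey[, 2L]))
    } else {
      character(0)
    }
    if (!all(key_x %in% key_y)) {
      warning(sum(!(key_x %in% key_y)),
              " edge(s) of the original network are absent from the ",
              "augmented network", call. = FALSE)
    }
  }
  structure(list(x = x, y = y, added = added), class = "augmented_pair")
}

#' @export
print.augmented_pair <- function(x, ...) {
  cat("Augmented network pair\n")
  cat(sprintf("  original : %d nodes, %d edges\n",
              igraph::vcount(x$x), igraph::ecount(x$x)))
  cat(sprintf("  augmented: %d nodes, %d edges\n",
              igraph::vcount(x$y), igraph::ecount(x$y)))
  cat(sprintf("  added    : %d node(s)\n", length(x$added)))
  invisible(x)
}

as_augmented_pair <- function(x, y = NULL) {
  if (inherits(x, "augmented_pair")) {
    return(x)
  }
  if (is.null(y)) {
    stop("provide an augmented_pair, or both an original and an augmented ",
         "network", call. = FALSE)
  }
  augmented_pair(x, y)
}
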