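#' Read an undirected network from a tab-separated edge list
#'
#' Parses the edge-list dialect used throughout this package: one record per
#' line, fields separated by tabs. A line `u<TAB>v` declares an (unweighted)
#' edge, `u<TAB>v<TAB>w` an edge of weight `w` (only honoured when
#' `weighted = TRUE`), and a single-token line `u` declares an isolated node.
#' Lines starting with `#` and blank lines are ignored. Node identifiers are
#' arbitrary non-whitespace strings.
#'
#' Isolated nodes are first-class citizens: in an augmented-network analysis
#' they generate Impasses and Breakthroughs, so the format must be able to
#' represent them.
#'
#' Duplicate edge lines with the same weight are collapsed to a single edge;
#' a duplicate with a conflicting weight is an error (silent resolution would
#' hide upstream data bugs). Self-loops and negative weights are rejected.
#'
#' @param file Path to a file, or a connection, or a character vector of
#'   two or more lines.
#' @param weighted Logical; read a third column as the edge weight. When
#'   `FALSE` every edge gets weight 1 and any third column is ignored.
#' @param text Character vector of lines to parse instead of reading
#'   `file` (mirrors the `text` argument of [utils::read.table()]).
#' @return An undirected [igraph::igraph] graph with a `name` vertex
#'   attribute and a `weight` edge attribute.
#' @seealso [write_edge_list()], [network_stats()]
#' @examples
#' g <- read_edge_list(c("1\t2", "2\t3", "7"))
#' igraph::vcount(g)  # 4: nodes 1, 2, 3 and the isolated node 7
#' @export
read_edge_list <- function(file, weighted = FALSE, text = NULL) {
  lines <- if (!is.null(text)) {
    text
  } else if (is.character(file) && length(file) > 1L) {
    file
  } else if (is.character(file) && length(file) == 1L && !file.exists(file) &&
             grepl("[\t\n]", file)) {
    strsplit(file, "\n", fixed = TRUE)[[1L]]
  } else {
    readLines(file, warn = FALSE)
  }
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(make_network(character(0), data.frame(from = character(0),
                                                 to = character(0),
                                                 weight = numeric(0))))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf < 1L | nf > 3L | vapply(fields, function(f) any(!nzchar(f)), logical(1))
  if (any(bad)) {
    stop("malformed edge-list line ", idx[which(bad)[1L]], ": ",
         dQuote(lines[idx[which(bad)[1L]]]), call. = FALSE)
  }
  singles <- nf == 1L
  iso <- vapply(fields[singles], `[[`, character(1), 1L)
  ef <- fields[!singles]
  eidx <- idx[!singles]
  from <- vapply(ef, `[[`, character(1), 1L)
  to <- vapply(ef, `[[`, character(1), 2L)
  w <- rep(1, length(ef))
  if (weighted) {
    has_w <- lengths(ef) == 3L
    wtxt <- vapply(ef[has_w], `[[`, character(1), 3L)
    wval <- suppressWarnings(as.numeric(wtxt))
    if (anyNA(wval)) {
      stop("non-numeric edge weight on line ", eidx[has_w][which(is.na(wval))[1L]],
           call. = FALSE)
    }
    if (any(wval < 0)) {
      stop("negative edge weight on line ", eidx[has_w][which(wval < 0)[1L]],
           call. = FALSE)
    }
    w[has_w] <- wval
  }
  if (any(from == to)) {
    stop("self-loop on line ", eidx[which(from == to)[1L]], call. = FALSE)
  }
  edges <- data.frame(from = from, to = to, weight = w,
                      stringsAsFactors = FALSE)
  make_network(iso, edges)
}

# Build a validated igraph from isolated nodes + an edge data frame.
# Collapses duplicate undirected edges with identical weight; conflicting
# duplicates are an error.
make_network <- function(isolated, edges) {
  key <- ifelse(edges$from < edges$to,
                paste(edges$from, edges$to, sep = "\r"),
                paste(edges$to, edges$from, sep = "\r"))
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    wref <- edges$weight[first][match(key, key[first])]
    if (any(abs(edges$weight - wref) > 0)) {
      bad <- key[which(abs(edges$weight - wref) > 0)[1L]]
      stop("duplicate edge ", gsub("\r", "-", bad),
           " with conflicting weights", call. = FALSE)
    }
    edges <- edges[first, , drop = FALSE]
  }
  nodes <- sort(unique(c(isolated, edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  g
}

#' Write a network as a tab-separated edge list
#'
#' Inverse of [read_edge_list()]: one edge per line, isolated nodes as
#' single-token lines, so that a read of the written file reproduces the
#' node set, edge set and weights exactly.
#'
#' @param net An undirected igraph graph with named vertices.
#' @param file Path or connection to write to.
#' @param weighted Write a third column holding edge weights.
#' @return Invisibly, the character vector of lines written.
#' @export
write_edge_list <- function(net, file, weighted = FALSE) {
  net <- as_brides_network(net)
  el <- igraph::as_edgelist(net)
  w <- igraph::E(net)$weight
  lines <- if (weighted) {
    sprintf("%s\t%s\t%s", el[, 1L], el[, 2L], format(w, trim = TRUE, digits = 15))
  } else {
    sprintf("%s\t%s", el[, 1L], el[, 2L])
  }
  deg <- igraph::degree(net)
  lines <- c(lines, names(deg)[deg == 0L])
  writeLines(lines, file)
  invisible(lines)
}

# Coerce/validate user input into the network representation used across the
# package: an undirected igraph with vertex names and nonnegative weights
# (weight 1 everywhere when the input carries no weight attribute).
as_brides_network <- function(net, arg = deparse(substitute(net))) {
  if (is.character(net)) {
    net <- read_edge_list(net)
  }
  if (!igraph::is_igraph(net)) {
    stop(arg, " must be an igraph graph or an edge-list file path", call. = FALSE)
  }
  if (igraph::is_directed(net)) {
    stop(arg, " must be undirected", call. = FALSE)
  }
  if (is.null(igraph::V(net)$name)) {
    igraph::V(net)$name <- as.character(seq_len(igraph::vcount(net)))
  }
  if (anyDuplicated(igraph::V(net)$name)) {
    stop(arg, " has duplicated node names", call. = FALSE)
  }
  if (is.null(igraph::E(net)$weight)) {
    igraph::E(net)$weight <- rep(1, igraph::ecount(net))
  }
  if (any(igraph::E(net)$weight < 0)) {
    stop(arg, " has negative edge weights", call. = FALSE)
  }
  if (igraph::any_loop(net) || igraph::any_multiple(net)) {
    stop(arg, " must be simple (no loops or multi-edges)", call. = FALSE)
  }
  net
}

#' Summary statistics of a network
#'
#' Computes the descriptors conventionally reported for genome similarity
#' networks: node and edge counts, average degree (2|E|/|N|), average
#' shortest-path length, and the mean local clustering coefficient.
#'
#' Genome similarity networks are typically disconnected, so the average
#' path length is taken over connected pairs only (it would otherwise be
#' infinite), and the clustering coefficient is the mean of local
#' coefficients with nodes of degree < 2 contributing 0. Distances are hop
#' counts for unweighted input and weighted shortest-path lengths otherwise.
#'
#' @param net An undirected igraph graph (or edge-list file path).
#' @return A one-row data frame with columns `nodes`, `edges`,
#'   `avg_degree`, `avg_path_length`, `clustering`.
#' @examples
#' network_stats(igraph::make_full_graph(3))
#' @export
network_stats <- function(net) {
  net <- as_brides_network(net)
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  apl <- if (n >= 2L) igraph::mean_distance(net, unconnected = TRUE) else NaN
  cc <- if (n >= 1L) {
    igraph::transitivity(net, type = "localaverage", isolates = "zero")
  } else {
    NaN
  }
  data.frame(nodes = n, edges = m,
             avg_degree = if (n > 0L) 2 * m / n else NaN,
             avg_path_length = apl,
             clustering = cc)
}
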