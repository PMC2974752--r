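#' Build a simple undirected protein-protein interaction network
#'
#' Constructs the network object all other functions operate on from a
#' two-column edge table (or an `igraph` graph). Self-loops are removed and
#' duplicate pairs -- in either orientation -- are collapsed to a single
#' edge, so the result is always a simple undirected graph.
#'
#' @param edges A data frame whose first two columns give the endpoints of
#'   each interaction (coerced to character), or an `igraph` object.
#' @param quiet If `FALSE` (default), report the number of self-loops and
#'   duplicate edges that were dropped.
#'
#' @return An object of class `ppi_network`: a list with elements
#'   `nodes` (sorted character vector of protein IDs), `adj` (adjacency
#'   list of integer node indices), `degree` (integer vector, parallel to
#'   `nodes`), and `m` (total edge count).
#'
#' @details Protein IDs are opaque, case-sensitive strings; no identifier
#'   mapping is performed. Isolated proteins cannot be represented in an
#'   edge list and are not needed: a protein with no interactions can never
#'   join a complex.
#'
#' @examples
#' net <- ppi_network(data.frame(a = c("p1", "p2", "p1"),
#'                               b = c("p2", "p3", "p1")))
#' net
#' @export
ppi_network <- function(edges, quiet = FALSE) {
  if (inherits(edges, "ppi_network")) {
    return(edges)
  }
  if (inherits(edges, "igraph")) {
    rlang::check_installed("igraph")
    el <- igraph::as_edgelist(edges, names = TRUE)
    edges <- tibble::tibble(from = as.character(el[, 1]),
                            to = as.character(el[, 2]))
  }
  if (!is.data.frame(edges) || ncol(edges) < 2) {
    rlang::abort("`edges` must be a data frame with at least two columns.")
  }
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  if (anyNA(from) || anyNA(to)) {
    rlang::abort("edge endpoints must not be NA")
  }
  keep <- from != to
  n_self <- sum(!keep)
  a <- pmin(from[keep], to[keep])
  b <- pmax(from[keep], to[keep])
  key <- paste0(a, "\r", b)
  dup <- duplicated(key)
  n_dup <- sum(dup)
  a <- a[!dup]
  b <- b[!dup]
  if (length(a) == 0L) {
    rlang::abort("empty network: no edges remain after cleaning")
  }
  if (!quiet && (n_self > 0L || n_dup > 0L)) {
    rlang::inform(sprintf("dropped %d self-loop(s) and %d duplicate edge(s)",
                          n_self, n_dup))
  }
  nodes <- sort(unique(c(a, b)))
  i <- match(a, nodes)
  j <- match(b, nodes)
  ends <- c(i, j)
  nbrs <- c(j, i)
  adj <- unname(split(nbrs, factor(ends, levels = seq_along(nodes))))
  adj <- lapply(adj, function(v) sort.int(as.integer(v)))
  structure(
    list(nodes = nodes,
         adj = adj,
         degree = lengths(adj),
         m = length(a)),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d proteins, %d interactions\n",
              length(x$nodes), x$m))
  invisible(x)
}

#' Edge table of a network
#'
#' @param net A `ppi_network`.
#' @return A tibble with columns `from` and `to` (with `from < to`), one row
#'   per edge, in deterministic order.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  i <- rep.int(seq_along(net$adj), net$degree)
  j <- unlist(net$adj, use.names = FALSE)
  keep <- i < j
  tibble::tibble(from = net$nodes[i[keep]], to = net$nodes[j[keep]])
}

#' @rdname network_edges
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  net$nodes
}

#' Node degrees
#'
#' Degrees are always taken in the full input network.
#'
#' @param net A `ppi_network`.
#' @param nodes Optional character vector of protein IDs; defaults to all.
#' @return Named integer vector of degrees.
#' @export
network_degree <- function(net, nodes = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  if (is.null(nodes)) {
    return(stats::setNames(net$degree, net$nodes))
  }
  idx <- node_index(net, nodes)
  stats::setNames(net$degree[idx], nodes)
}

# resolve protein IDs to integer indices, erroring on unknown IDs
node_index <- function(net, nodes) {
  idx <- match(nodes, net$nodes)
  if (anyNA(idx)) {
    rlang::abort(sprintf("unknown protein ID(s): %s",
                         paste(nodes[is.na(idx)], collapse = ", ")))
  }
  idx
}

# number of edges with both endpoints in the index set `idx`
intra_edge_count <- function(net, idx) {
  if (length(idx) < 2L) return(0L)
  in_set <- logical(length(net$nodes))
  in_set[idx] <- TRUE
  tot <- 0L
  for (v in idx) {
    tot <- tot + sum(in_set[net$adj[[v]]])
  }
  tot %/% 2L
}

# number of edges from node index v into the index set (v excluded)
edges_into <- function(net, v, idx_flag) {
  sum(idx_flag[net$adj[[v]]])
}
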