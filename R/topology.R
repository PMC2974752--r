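#' Topological overlap of two proteins
#'
#' Edge weight used for seed construction. For adjacent proteins `v`, `w` it
#' is the number of neighbours they share, normalised by the average of
#' their degrees:
#' \deqn{O_T(v, w) = A_{vw} \, |\Gamma(v, w)| \, / \, ((k_v + k_w)/2)}
#' where \eqn{A_{vw}} is the adjacency indicator and \eqn{\Gamma(v, w)} the
#' set of common neighbours (never containing `v` or `w` themselves).
#' Non-adjacent pairs have weight 0.
#'
#' The average-degree normalisation (rather than the classical
#' \eqn{\min(k_v, k_w)}) keeps a low-degree protein sharing three partners
#' with a 100-interaction hub from being scored as topologically identical
#' to the hub.
#'
#' @param net A [ppi_network].
#' @param v,w Protein IDs (must be distinct and present in the network).
#' @return A weight in `[0, 1]`.
#' @examples
#' k3 <- ppi_network(data.frame(a = c("a", "a", "b"), b = c("b", "c", "c")))
#' topological_overlap(k3, "a", "b")  # 0.5
#' @export
topological_overlap <- function(net, v, w) {
  stopifnot(inherits(net, "ppi_network"))
  if (identical(v, w)) {
    rlang::abort("`v` and `w` must be distinct proteins")
  }
  iv <- node_index(net, v)
  iw <- node_index(net, w)
  if (!(iw %in% net$adj[[iv]])) {
    return(0)
  }
  n_common <- length(intersect(net$adj[[iv]], net$adj[[iw]]))
  n_common / ((net$degree[iv] + net$degree[iw]) / 2)
}

#' Topological-overlap weights for every edge
#'
#' @param net A [ppi_network].
#' @return A tibble with columns `from`, `to` (`from < to`) and `weight`,
#'   one row per edge. A weight is 0 exactly when the edge's endpoints share
#'   no common neighbour.
#' @export
weight_edges <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  edges <- network_edges(net)
  if (nrow(edges) == 0L) {
    return(tibble::tibble(from = character(), to = character(),
                          weight = double()))
  }
  i <- match(edges$from, net$nodes)
  j <- match(edges$to, net$nodes)
  w <- double(length(i))
  for (e in seq_along(i)) {
    n_common <- length(intersect(net$adj[[i[e]]], net$adj[[j[e]]]))
    w[e] <- n_common / ((net$degree[i[e]] + net$degree[j[e]]) / 2)
  }
  edges$weight <- w
  edges
}

#' Enumerate all triangles of a network
#'
#' Edge-iterator scheme: iterate over the edges of a working copy of the
#' graph; for each edge emit one triangle per common neighbour of its
#' endpoints, then delete the edge from the working copy so no triangle is
#' reported twice. Runs in `O(k_max * m)` time. The input network is not
#' modified.
#'
#' @param net A [ppi_network].
#' @return A tibble with character columns `v`, `w`, `x`, one row per
#'   triangle, members sorted within each row, rows in deterministic order.
#' @export
enumerate_triangles <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  adj <- net$adj # working copy; mutated below, net itself untouched
  out_v <- integer(0)
  out_w <- integer(0)
  out_x <- integer(0)
  for (i in seq_along(adj)) {
    js <- adj[[i]]
    js <- js[js > i]
    for (j in js) {
      common <- intersect(adj[[i]], adj[[j]])
      if (length(common) > 0L) {
        out_v <- c(out_v, rep.int(i, length(common)))
        out_w <- c(out_w, rep.int(j, length(common)))
        out_x <- c(out_x, common)
      }
      # delete edge {i, j} from the working copy
      adj[[i]] <- adj[[i]][adj[[i]] != j]
      adj[[j]] <- adj[[j]][adj[[j]] != i]
    }
  }
  if (length(out_v) == 0L) {
    return(tibble::tibble(v = character(), w = character(), x = character()))
  }
  trip <- apply(cbind(out_v, out_w, out_x), 1L, sort.int)
  tibble::tibble(v = net$nodes[trip[1L, ]],
                 w = net$nodes[trip[2L, ]],
                 x = net$nodes[trip[3L, ]])
}

#' Rank triangle seeds by averaged edge weight
#'
#' Each triangle's seed weight is the mean of its three pairwise
#' topological-overlap edge weights. Seeds are sorted by weight descending;
#' ties are broken lexicographically on the sorted member triple, so the
#' ranking is deterministic. Zero-weight seeds (triangles whose edges share
#' no further neighbours) are kept and rank last.
#'
#' @param triangles A tibble as returned by [enumerate_triangles()].
#' @param weights An edge-weight tibble as returned by [weight_edges()].
#' @return A tibble with columns `v`, `w`, `x`, `weight`, ordered.
#' @export
rank_seeds <- function(triangles, weights) {
  stopifnot(is.data.frame(triangles), is.data.frame(weights))
  if (nrow(triangles) == 0L) {
    return(tibble::tibble(v = character(), w = character(), x = character(),
                          weight = double()))
  }
  wkey <- stats::setNames(weights$weight,
                          paste0(weights$from, "\r", weights$to))
  lookup <- function(a, b) {
    k <- paste0(pmin(a, b), "\r", pmax(a, b))
    w <- wkey[k]
    if (anyNA(w)) {
      rlang::abort("missing edge weight for a triangle edge")
    }
    unname(w)
  }
  sw <- (lookup(triangles$v, triangles$w) +
           lookup(triangles$v, triangles$x) +
           lookup(triangles$w, triangles$x)) / 3
  out <- tibble::tibble(v = triangles$v, w = triangles$w, x = triangles$x,
                        weight = sw)
  out[order(-out$weight, out$v, out$w, out$x), , drop = FALSE]
}
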