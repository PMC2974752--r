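# small graphs and brute-force oracles used across tests

edge_df <- function(...) {
  v <- c(...)
  stopifnot(length(v) %% 2 == 0)
  idx <- seq(1, length(v), by = 2)
  tibble::tibble(from = v[idx], to = v[idx + 1])
}

complete_edges <- function(ids) {
  p <- utils::combn(sort(ids), 2)
  tibble::tibble(from = p[1, ], to = p[2, ])
}

path_edges <- function(ids) {
  tibble::tibble(from = ids[-length(ids)], to = ids[-1])
}

# two K3s {a,b,c} and {d,e,f} joined by the bridge c-d
two_k3_bridge <- function() {
  ppi_network(dplyr::bind_rows(complete_edges(c("a", "b", "c")),
                               complete_edges(c("d", "e", "f")),
                               edge_df("c", "d")),
              quiet = TRUE)
}

two_k3_disjoint <- function() {
  ppi_network(dplyr::bind_rows(complete_edges(c("a", "b", "c")),
                               complete_edges(c("d", "e", "f"))),
              quiet = TRUE)
}

# G(n, p) edge table with deterministic node names and seed
random_edge_df <- function(n, p, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("n%03d", seq_len(n))
    pairs <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pairs)) < p
    tibble::tibble(from = ids[pairs[1, keep]], to = ids[pairs[2, keep]])
  })
}

# random G(n, p) that is guaranteed non-empty
random_network <- function(n, p, seed) {
  e <- random_edge_df(n, p, seed)
  while (nrow(e) == 0) {
    seed <- seed + 1000
    e <- random_edge_df(n, p, seed)
  }
  ppi_network(e, quiet = TRUE)
}

# brute-force triangle enumeration over all C(n, 3) node triples
brute_triangles <- function(net) {
  ids <- network_nodes(net)
  if (length(ids) < 3) return(character(0))
  trips <- utils::combn(ids, 3)
  is_edge <- function(a, b) {
    ai <- match(a, net$nodes)
    match(b, net$nodes) %in% net$adj[[ai]]
  }
  keep <- vapply(seq_len(ncol(trips)), function(k) {
    t <- trips[, k]
    is_edge(t[1], t[2]) && is_edge(t[1], t[3]) && is_edge(t[2], t[3])
  }, TRUE)
  apply(trips[, keep, drop = FALSE], 2, paste, collapse = "|")
}

# exact hypergeometric upper tail by direct summation of the pmf
brute_hyper_tail <- function(x, K, N, n) {
  ks <- x:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
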