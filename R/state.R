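#' Growing sub-network state with cached modularity gains
#'
#' The greedy search keeps, for a candidate complex `S`, its intra-edge
#' count `m_SS`, degree sum `d_S`, neighbour frontier `N_S` and a cache of
#' \eqn{\Delta LQ_\alpha(v, S)} for every frontier protein `v`. The cache is
#' maintained incrementally across merges (see
#' [update_deltas_after_merge()]) so each merge costs `O(d_S)` instead of a
#' full recomputation.
#'
#' @param net A [ppi_network].
#' @param members Character vector of protein IDs forming `S`.
#' @param alpha Coarseness parameter in `[0, 1]`.
#' @return An object of class `subnetwork_state` with elements `members`
#'   (sorted character), `m_ss`, `d_s`, `neighbors` (sorted character) and
#'   `delta` (named numeric over `neighbors`), plus `alpha` and the network.
#' @export
subnetwork_state <- function(net, members, alpha) {
  stopifnot(inherits(net, "ppi_network"))
  check_alpha(alpha)
  idx <- sort.int(node_index(net, unique(members)))
  flag <- logical(length(net$nodes))
  flag[idx] <- TRUE
  nbr <- sort.int(setdiff(unique(unlist(net$adj[idx], use.names = FALSE)),
                          idx))
  m <- net$m
  pen <- 2 * m^alpha
  d_s <- sum(net$degree[idx])
  delta <- vapply(nbr, function(v) {
    (1 / m) * (edges_into(net, v, flag) - net$degree[v] * d_s / pen)
  }, 0)
  structure(
    list(net = net,
         alpha = alpha,
         idx = idx,
         nbr = nbr,
         delta = unname(delta),
         m_ss = intra_edge_count(net, idx),
         d_s = d_s),
    class = "subnetwork_state"
  )
}

#' @export
print.subnetwork_state <- function(x, ...) {
  cat(sprintf(
    "<subnetwork_state> %d members, m_SS = %d, d_S = %d, %d neighbors (alpha = %g)\n",
    length(x$idx), x$m_ss, x$d_s, length(x$nbr), x$alpha))
  cat("members:", paste(state_members(x), collapse = " "), "\n")
  invisible(x)
}

#' Accessors for a sub-network state
#'
#' @param state A `subnetwork_state`.
#' @return `state_members()` / `state_neighbors()`: sorted character vectors
#'   of protein IDs; `state_deltas()`: named numeric vector of cached
#'   \eqn{\Delta LQ_\alpha} values over the frontier.
#' @export
state_members <- function(state) {
  state$net$nodes[state$idx]
}

#' @rdname state_members
#' @export
state_neighbors <- function(state) {
  state$net$nodes[state$nbr]
}

#' @rdname state_members
#' @export
state_deltas <- function(state) {
  stats::setNames(state$delta, state$net$nodes[state$nbr])
}

#' Merge a frontier protein into the sub-network, updating cached gains
#'
#' Exploits the recursion between gains before and after a merge: for a
#' retained frontier protein `v`,
#' \eqn{\Delta LQ_\alpha(v, S') = \Delta LQ_\alpha(v, S) +
#' \Delta LQ_\alpha(v, \{v^*\})}; for a protein that becomes reachable only
#' through `v*`,
#' \eqn{\Delta LQ_\alpha(v, S') = -d_v d_S / (2 m^{\alpha+1}) +
#' \Delta LQ_\alpha(v, \{v^*\})}
#' with `d_S` the pre-merge degree sum. Both identities follow from the
#' linearity of the gain in `m_vS` and `d_S`.
#'
#' @param state A `subnetwork_state` whose cache is valid for `S`.
#' @param v_star A protein ID in the frontier `N_S`.
#' @return The updated `subnetwork_state` for `S' = S + v*`.
#' @export
update_deltas_after_merge <- function(state, v_star) {
  stopifnot(inherits(state, "subnetwork_state"))
  net <- state$net
  iv <- node_index(net, v_star)
  pos <- match(iv, state$nbr)
  if (is.na(pos)) {
    rlang::abort("`v_star` is not a frontier neighbor of the sub-network")
  }
  m <- net$m
  alpha <- state$alpha
  pen <- 2 * m^alpha
  d_vstar <- net$degree[iv]
  nb_vstar <- net$adj[[iv]]

  in_s <- logical(length(net$nodes))
  in_s[state$idx] <- TRUE
  m_vstar_s <- sum(in_s[nb_vstar])

  retained <- state$nbr[-pos]
  delta_ret <- state$delta[-pos]
  if (length(retained) > 0L) {
    a_vv <- as.numeric(retained %in% nb_vstar)
    delta_ret <- delta_ret +
      (1 / m) * (a_vv - net$degree[retained] * d_vstar / pen)
  }

  fresh <- setdiff(nb_vstar, c(state$nbr, state$idx))
  if (length(fresh) > 0L) {
    delta_new <- -net$degree[fresh] * state$d_s / (2 * m^(alpha + 1)) +
      (1 / m) * (1 - net$degree[fresh] * d_vstar / pen)
  } else {
    delta_new <- double(0)
  }

  nbr2 <- c(retained, fresh)
  delta2 <- c(delta_ret, delta_new)
  ord <- order(nbr2)

  structure(
    list(net = net,
         alpha = alpha,
         idx = sort.int(c(state$idx, iv)),
         nbr = nbr2[ord],
         delta = unname(delta2[ord]),
         m_ss = state$m_ss + m_vstar_s,
         d_s = state$d_s + d_vstar),
    class = "subnetwork_state"
  )
}
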