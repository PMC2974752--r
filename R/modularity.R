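#' Global (Newman-Girvan) modularity of a partition
#'
#' \deqn{Q = \sum_s \left[ m_{ss}/m - (d_s/2m)^2 \right]}
#' where `m` is the total edge count, `m_ss` the number of intra-module
#' edges of module `s` and `d_s` the sum of its members' degrees in the full
#' network. The second term is the expected within-module edge fraction
#' under a degree-preserving configuration model; because that expectation
#' is computed against the whole network, `Q` has a resolution limit for
#' small sub-networks such as protein complexes.
#'
#' @param net A [ppi_network].
#' @param partition A list of disjoint character vectors of protein IDs
#'   (their union need not cover the network).
#' @return The modularity `Q` (a scalar, at most 1).
#' @export
global_modularity <- function(net, partition) {
  stopifnot(inherits(net, "ppi_network"), is.list(partition))
  if (length(partition) == 0L) return(0)
  all_ids <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    rlang::abort("partition blocks must be disjoint")
  }
  sum(vapply(partition, function(s) {
    idx <- node_index(net, s)
    m_ss <- intra_edge_count(net, idx)
    d_s <- sum(net$degree[idx])
    m_ss / net$m - (d_s / (2 * net$m))^2
  }, 0))
}

#' Local modularity of Muff et al.
#'
#' A local variant of modularity in which each module's edge fractions are
#' computed against its immediate neighbourhood instead of the whole
#' network:
#' \deqn{LQ = \sum_s \left[ m_{ss}/m_s - (d_s/2m_s)^2 \right]}
#' Here `m_s` counts the edges with at least one endpoint in module `s`
#' (edges lying entirely among the first neighbours are excluded; see the
#' package vignette for a discussion of this convention). Provided as a
#' comparison utility; the search itself uses [lq_alpha()].
#'
#' @inheritParams global_modularity
#' @param modules A list of disjoint character vectors.
#' @return The local modularity `LQ`.
#' @export
local_modularity_muff <- function(net, modules) {
  stopifnot(inherits(net, "ppi_network"), is.list(modules))
  if (length(modules) == 0L) return(0)
  all_ids <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    rlang::abort("modules must be disjoint")
  }
  sum(vapply(modules, function(s) {
    idx <- node_index(net, s)
    m_ss <- intra_edge_count(net, idx)
    d_s <- sum(net$degree[idx])
    m_s <- d_s - m_ss # edges with >= 1 endpoint in the module
    if (m_s == 0) {
      rlang::warn("module with no incident edges: term skipped")
      return(0)
    }
    m_ss / m_s - (d_s / (2 * m_s))^2
  }, 0))
}

#' Parametric local modularity of a single sub-network
#'
#' The score the greedy search maximises:
#' \deqn{LQ_\alpha = m_{SS}/m - \left(d_S / (2 m^{(\alpha+1)/2})\right)^2,
#'   \quad 0 \le \alpha \le 1}
#' The coarseness parameter \eqn{\alpha} tunes the effective background
#' neighbourhood used for the expected-edges term: \eqn{\alpha = 1} recovers
#' the global-modularity term for a single module, while smaller
#' \eqn{\alpha} shrinks the neighbourhood (edge-coverage ratio
#' \eqn{r = m^{\alpha - 1}}) and penalises large sub-networks more heavily.
#'
#' @param net A [ppi_network].
#' @param members Character vector of protein IDs (non-empty).
#' @param alpha Coarseness parameter in `[0, 1]`.
#' @return The scalar score.
#' @export
lq_alpha <- function(net, members, alpha) {
  stopifnot(inherits(net, "ppi_network"))
  check_alpha(alpha)
  if (length(members) == 0L) {
    rlang::abort("`members` must be non-empty")
  }
  if (net$m == 0) rlang::abort("network has no edges")
  idx <- node_index(net, unique(members))
  m_ss <- intra_edge_count(net, idx)
  d_s <- sum(net$degree[idx])
  m_ss / net$m - (d_s / (2 * net$m^((alpha + 1) / 2)))^2
}

#' Gain in parametric local modularity from merging one protein
#'
#' \deqn{\Delta LQ_\alpha(v, S) = \frac{1}{m}\left(m_{vS} -
#'   \frac{d_v d_S}{2 m^\alpha}\right)}
#' where `m_vS` is the number of edges from `v` into `S`, and `d_v`, `d_S`
#' are degrees in the full network. This is the greedy criterion; at
#' \eqn{\alpha = 1} it equals the global-modularity gain \eqn{\Delta Q}.
#'
#' @param net A [ppi_network].
#' @param v A protein ID not in `members`.
#' @param members Character vector of protein IDs (the sub-network `S`).
#' @param alpha Coarseness parameter in `[0, 1]`.
#' @return The scalar gain.
#' @export
delta_lq_alpha <- function(net, v, members, alpha) {
  stopifnot(inherits(net, "ppi_network"))
  check_alpha(alpha)
  if (v %in% members) {
    rlang::abort("`v` must not already belong to the sub-network")
  }
  iv <- node_index(net, v)
  idx <- node_index(net, unique(members))
  flag <- logical(length(net$nodes))
  flag[idx] <- TRUE
  m_vs <- edges_into(net, iv, flag)
  d_s <- sum(net$degree[idx])
  (1 / net$m) * (m_vs - net$degree[iv] * d_s / (2 * net$m^alpha))
}

#' @rdname delta_lq_alpha
#' @details `delta_q()` is the global-modularity merge gain
#'   \eqn{\Delta Q(v, S) = (1/m)(m_{vS} - d_v d_S / 2m)}, i.e.
#'   `delta_lq_alpha()` at `alpha = 1`.
#' @export
delta_q <- function(net, v, members) {
  delta_lq_alpha(net, v, members, alpha = 1)
}

#' Edge-coverage ratio of the coarseness parameter
#'
#' The fraction of the network's edges effectively used as background at a
#' given coarseness: \eqn{r = 2 m^\alpha / 2m = m^{\alpha - 1}}.
#' `alpha_for_coverage()` is the inverse, \eqn{\alpha = 1 + \log_m r}, so a
#' desired local coverage (say 50 percent of edges) can be translated into
#' an `alpha`.
#'
#' @param alpha Coarseness parameter in `[0, 1]`.
#' @param m Total edge count (at least 2).
#' @param r Edge-coverage ratio in `(0, 1]`.
#' @return `edge_coverage_ratio()` returns `r`; `alpha_for_coverage()`
#'   returns `alpha`.
#' @export
edge_coverage_ratio <- function(alpha, m) {
  check_alpha(alpha)
  check_m(m)
  m^(alpha - 1)
}

#' @rdname edge_coverage_ratio
#' @export
alpha_for_coverage <- function(r, m) {
  check_m(m)
  if (any(r <= 0 | r > 1)) {
    rlang::abort("`r` must lie in (0, 1]")
  }
  1 + log(r) / log(m)
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    rlang::abort("`alpha` must be a single number in [0, 1]")
  }
}

check_m <- function(m) {
  if (!is.numeric(m) || any(m < 2)) {
    rlang::abort("`m` must be at least 2")
  }
}
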