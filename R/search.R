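#' Expand a triangle seed by greedy local-modularity maximisation
#'
#' Starting from a triangle seed `S`, repeatedly merges the frontier
#' protein with the largest \eqn{\Delta LQ_\alpha(v, S)} while that maximum
#' is non-negative; the search stops as soon as the maximum gain is
#' strictly negative (so a candidate whose best gain is exactly 0 keeps
#' growing) or the frontier is empty. Gains are maintained incrementally
#' via [update_deltas_after_merge()]. Ties in the argmax are broken by the
#' lexicographically smallest protein ID, making the expansion
#' deterministic.
#'
#' @param net A [ppi_network].
#' @param seed Character vector of three protein IDs forming a triangle in
#'   `net` (a one-row tibble with columns `v`, `w`, `x` also works).
#' @param alpha Coarseness parameter in `[0, 1]`.
#' @return The final [subnetwork_state]; `state_members()` gives the grown
#'   candidate complex.
#' @export
grow_seed <- function(net, seed, alpha) {
  stopifnot(inherits(net, "ppi_network"))
  if (is.data.frame(seed)) {
    seed <- c(seed$v[1], seed$w[1], seed$x[1])
  }
  seed <- unique(as.character(seed))
  if (length(seed) != 3L) {
    rlang::abort("`seed` must consist of three distinct proteins")
  }
  idx <- node_index(net, seed)
  is_tri <- all(idx[2] %in% net$adj[[idx[1]]],
                idx[3] %in% net$adj[[idx[1]]],
                idx[3] %in% net$adj[[idx[2]]])
  if (!is_tri) {
    rlang::abort("`seed` is not a triangle of the network")
  }
  state <- subnetwork_state(net, seed, alpha)
  while (length(state$nbr) > 0L) {
    best <- max(state$delta)
    if (best < 0) {
      # cached gains drift by ~1e-15 per merge; near the strict-zero
      # boundary, re-derive them directly before committing to a stop
      if (best > -1e-9) {
        state <- subnetwork_state(net, state_members(state), alpha)
        best <- if (length(state$nbr) > 0L) max(state$delta) else -Inf
      }
      if (best < 0) break
    }
    cand <- state$nbr[state$delta == best]
    v_star <- state$net$nodes[min(cand)] # nodes sorted: min index = lex smallest
    state <- update_deltas_after_merge(state, v_star)
  }
  state
}

#' Overlap score between two member sets
#'
#' \eqn{|S \cap T| / \min(|S|, |T|)}; complexes scoring above 0.5 are
#' merged by [merge_complexes()].
#'
#' @param s,t Non-empty character vectors of protein IDs.
#' @return A score in `[0, 1]`.
#' @export
overlap_score <- function(s, t) {
  s <- unique(s)
  t <- unique(t)
  if (length(s) == 0L || length(t) == 0L) {
    rlang::abort("overlap score of an empty set is undefined")
  }
  length(intersect(s, t)) / min(length(s), length(t))
}

#' Merge overlapping candidate complexes
#'
#' Agglomerates highest-overlap-first: while any pair of member sets has an
#' overlap score strictly greater than 0.5, the pair with the highest score
#' is replaced by its union, and all scores involving the union are
#' recomputed before the next decision. Ties are broken by the smaller
#' combined size, then lexicographically, so the result is independent of
#' input order. Pairs scoring exactly 0.5 are never merged.
#'
#' @param complexes A list of character member vectors.
#' @return A list of merged member sets (sorted members, deterministic
#'   order) in which no pair has overlap score above 0.5.
#' @export
merge_complexes <- function(complexes) {
  sets <- lapply(complexes, function(s) sort(unique(as.character(s))))
  if (length(sets) >= 2L) {
    fast_score <- function(a, b) {
      length(intersect(a, b)) / min(length(a), length(b))
    }
    n <- length(sets)
    score <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        score[i, j] <- fast_score(sets[[i]], sets[[j]])
      }
    }
    repeat {
      mx <- max(score)
      if (mx <= 0.5) break
      cand <- which(score == mx, arr.ind = TRUE)
      if (nrow(cand) > 1L) {
        # ties: smaller combined size first, then lexicographic on content
        csize <- lengths(sets)[cand[, 1L]] + lengths(sets)[cand[, 2L]]
        cand <- cand[csize == min(csize), , drop = FALSE]
        if (nrow(cand) > 1L) {
          tags <- vapply(seq_len(nrow(cand)), function(k) {
            paste(sort(c(paste(sets[[cand[k, 1L]]], collapse = " "),
                         paste(sets[[cand[k, 2L]]], collapse = " "))),
                  collapse = "|")
          }, "")
          cand <- cand[order(tags), , drop = FALSE]
        }
      }
      i <- cand[1L, 1L]
      j <- cand[1L, 2L]
      sets[[i]] <- sort(union(sets[[i]], sets[[j]]))
      sets[[j]] <- NULL
      score <- score[-j, -j, drop = FALSE]
      n <- length(sets)
      if (n < 2L) break
      for (k in seq_len(n)) {
        if (k == i) next
        s <- fast_score(sets[[i]], sets[[k]])
        score[min(i, k), max(i, k)] <- s
      }
    }
  }
  sets[order(vapply(sets, paste, "", collapse = " "))]
}

#' Density score of a member set
#'
#' The product of a sub-network's edge density and its size:
#' \deqn{\delta_s = \frac{m_{ss}}{n_s (n_s - 1)/2} \cdot n_s}
#' A clique of size `n` scores `n`; sparse sub-networks score low. Used as
#' the final filter of the pipeline (complexes with
#' \eqn{\delta_s < \delta} are discarded; equality is kept).
#'
#' @param net A [ppi_network].
#' @param members Character vector of at least two protein IDs.
#' @return The scalar score, in `(0, n_s]` for connected sets.
#' @export
density_score <- function(net, members) {
  stopifnot(inherits(net, "ppi_network"))
  members <- unique(as.character(members))
  n_s <- length(members)
  if (n_s < 2L) {
    rlang::abort("density score requires at least two members")
  }
  m_ss <- intra_edge_count(net, node_index(net, members))
  m_ss / (n_s * (n_s - 1) / 2) * n_s
}

#' Predict protein complexes from a PPI network
#'
#' The full pipeline: (1) weight every edge by topological overlap;
#' (2) enumerate all triangles and rank them as seeds by mean edge weight;
#' (3) for each seed not already covered by an earlier result, expand it
#' with [grow_seed()]; seeds that fail to grow beyond their three members
#' are unpromising and discarded; (4) merge candidates whose overlap score
#' exceeds 0.5; (5) recompute density scores on the merged member sets and
#' drop complexes with \eqn{\delta_s < \delta}. The run is deterministic:
#' repeated calls on the same input give identical output.
#'
#' A triangle counts as covered when all three of its proteins lie inside a
#' single previously grown candidate; this permits overlapping complexes
#' while avoiding redundant searches.
#'
#' @param net A [ppi_network] (or an edge data frame, which is converted).
#' @param alpha Coarseness parameter in `[0, 1]`.
#' @param delta Density-score threshold (>= 0).
#' @param refine Reserved hook for a post-expansion refinement pass around
#'   each candidate; the default (and currently only) behaviour is no
#'   refinement.
#' @return An object of class `mipalm_fit` with a `complexes` tibble
#'   (columns `complex`, `size`, `n_edges`, `density_score`, `members`
#'   list-column) and a `stats` list of per-stage counts. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' sim <- generate_synthetic(synthetic_spec(n_complexes = 3,
#'                                          background_nodes = 40,
#'                                          seed = 7))
#' fit <- run_mipalm(sim$network, alpha = 0.5, delta = 2)
#' fit
#' @export
run_mipalm <- function(net, alpha, delta, refine = FALSE) {
  net <- ppi_network(net)
  check_alpha(alpha)
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0) {
    rlang::abort("`delta` must be a single non-negative number")
  }

  weights <- weight_edges(net)
  triangles <- enumerate_triangles(net)
  if (nrow(triangles) == 0L) {
    rlang::warn("no triangles in network: no seeds to expand")
    return(new_mipalm_fit(tibble::tibble(complex = character(),
                                         size = integer(),
                                         n_edges = integer(),
                                         density_score = double(),
                                         members = list()),
                          alpha, delta, refine,
                          list(n_seeds = 0L, n_covered = 0L, n_grown = 0L,
                               n_size3_discarded = 0L, n_candidates = 0L,
                               n_after_merge = 0L, n_filtered = 0L)))
  }
  seeds <- rank_seeds(triangles, weights)

  found <- list()    # every grown member set, for seed coverage
  candidates <- list() # grown sets with > 3 members
  n_covered <- 0L
  n_size3 <- 0L
  for (k in seq_len(nrow(seeds))) {
    trio <- c(seeds$v[k], seeds$w[k], seeds$x[k])
    covered <- any(vapply(found, function(s) all(trio %in% s), TRUE))
    if (covered) {
      n_covered <- n_covered + 1L
      next
    }
    state <- grow_seed(net, trio, alpha)
    mem <- state_members(state)
    found[[length(found) + 1L]] <- mem
    if (length(mem) == 3L) {
      n_size3 <- n_size3 + 1L
    } else {
      candidates[[length(candidates) + 1L]] <- mem
    }
  }

  merged <- merge_complexes(candidates)
  dscore <- vapply(merged, function(s) density_score(net, s), 0)
  keep <- dscore >= delta
  n_filtered <- sum(!keep)
  merged <- merged[keep]
  dscore <- dscore[keep]

  ord <- order(-dscore, vapply(merged, paste, "", collapse = " "))
  merged <- merged[ord]
  dscore <- dscore[ord]
  n_edges <- vapply(merged, function(s) {
    intra_edge_count(net, node_index(net, s))
  }, 0L)

  complexes <- tibble::tibble(
    complex = if (length(merged)) paste0("M", seq_along(merged)) else character(),
    size = lengths(merged),
    n_edges = as.integer(n_edges),
    density_score = dscore,
    members = merged
  )
  new_mipalm_fit(complexes, alpha, delta, refine,
                 list(n_seeds = nrow(seeds),
                      n_covered = n_covered,
                      n_grown = length(found),
                      n_size3_discarded = n_size3,
                      n_candidates = length(candidates),
                      n_after_merge = length(merged) + n_filtered,
                      n_filtered = n_filtered))
}

new_mipalm_fit <- function(complexes, alpha, delta, refine, stats) {
  structure(
    list(complexes = complexes, alpha = alpha, delta = delta,
         refine = refine, stats = stats),
    class = "mipalm_fit"
  )
}

#' @export
print.mipalm_fit <- function(x, ...) {
  cat(sprintf("miPALM fit (alpha = %g, delta = %g)\n", x$alpha, x$delta))
  cat(sprintf("  seeds: %d (%d covered, %d unpromising size-3)\n",
              x$stats$n_seeds, x$stats$n_covered, x$stats$n_size3_discarded))
  cat(sprintf("  candidates: %d -> %d after merging -> %d after density filter\n",
              x$stats$n_candidates, x$stats$n_after_merge,
              nrow(x$complexes)))
  if (nrow(x$complexes) > 0L) {
    print(utils::head(x$complexes, 10))
  }
  invisible(x)
}

#' Extract predicted member sets from a fit or catalog
#'
#' @param x A `mipalm_fit`, a catalog tibble with a `members` list-column,
#'   or a bare list of character vectors.
#' @return A list of character member vectors.
#' @export
complex_members <- function(x) {
  if (inherits(x, "mipalm_fit")) return(x$complexes$members)
  if (is.data.frame(x)) return(x$members)
  if (is.list(x)) return(lapply(x, as.character))
  rlang::abort("cannot extract complex members from this object")
}

#' Tune the coarseness and density parameters against a gold standard
#'
#' Grid search maximising the F-measure at matching threshold `omega`:
#' first a coarse sweep of `alpha` over `[0, 1]` in steps of 0.01 with the
#' density filter off, then a refinement in steps of 0.001 within 0.01 of
#' the coarse optimum, then a sweep of `delta` over `[0, 3.5]` in steps of
#' 0.01 at the chosen `alpha`. Because the density filter is the last
#' pipeline stage, the `delta` sweep reuses a single unfiltered run. Ties
#' prefer the smallest `alpha`, then the smallest `delta`.
#'
#' @param net A [ppi_network].
#' @param gold A complex catalog (see [read_complex_catalog()]) or list of
#'   member vectors; must be non-empty.
#' @param omega Matching-score threshold used in the F-measure.
#' @param alpha_step,alpha_fine_step,delta_step,delta_max Grid geometry.
#' @return An object of class `mipalm_tuning`: list with `alpha`, `delta`,
#'   `f_measure`, and tibbles `alpha_trace` / `delta_trace` of the grids.
#' @export
tune_mipalm <- function(net, gold, omega = 0.2,
                        alpha_step = 0.01, alpha_fine_step = 0.001,
                        delta_step = 0.01, delta_max = 3.5) {
  net <- ppi_network(net)
  gold_sets <- complex_members(gold)
  if (length(gold_sets) == 0L) {
    rlang::abort("gold-standard catalog is empty")
  }

  f_for_fit <- function(fit, dmin = NULL) {
    sets <- fit$complexes$members
    if (!is.null(dmin)) sets <- sets[fit$complexes$density_score >= dmin]
    if (length(sets) == 0L) return(0)
    evaluate_complexes(sets, gold_sets, threshold = omega)$f_measure
  }

  sweep_alpha <- function(grid) {
    fs <- vapply(grid, function(a) {
      f_for_fit(suppressWarnings(run_mipalm(net, alpha = a, delta = 0)))
    }, 0)
    tibble::tibble(alpha = grid, f_measure = fs)
  }

  coarse <- sweep_alpha(seq(0, 1, by = alpha_step))
  a0 <- coarse$alpha[which.max(coarse$f_measure)] # which.max: first = smallest
  fine_grid <- seq(max(0, a0 - alpha_step), min(1, a0 + alpha_step),
                   by = alpha_fine_step)
  fine <- sweep_alpha(fine_grid)
  alpha_trace <- dplyr::bind_rows(
    dplyr::mutate(coarse, stage = "coarse"),
    dplyr::mutate(fine, stage = "fine")
  )
  best_alpha <- fine$alpha[which.max(fine$f_measure)]

  fit0 <- suppressWarnings(run_mipalm(net, alpha = best_alpha, delta = 0))
  dgrid <- seq(0, delta_max, by = delta_step)
  dfs <- vapply(dgrid, function(d) f_for_fit(fit0, dmin = d), 0)
  delta_trace <- tibble::tibble(delta = dgrid, f_measure = dfs)
  best_delta <- dgrid[which.max(dfs)]

  structure(
    list(alpha = best_alpha, delta = best_delta,
         f_measure = max(dfs),
         alpha_trace = alpha_trace, delta_trace = delta_trace),
    class = "mipalm_tuning"
  )
}

#' @export
print.mipalm_tuning <- function(x, ...) {
  cat(sprintf("miPALM tuning: alpha = %g, delta = %g (F = %.4f)\n",
              x$alpha, x$delta, x$f_measure))
  invisible(x)
}
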