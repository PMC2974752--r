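test_that("greedy expansion recovers an isolated planted clique exactly", {
  # K6 clique disconnected from a sparse background; the background must be
  # large enough that the alpha = 0.5 penalty 5 * d_S / (2 sqrt(m)) stays
  # below the 3 intra-clique edges of the first merge (m > 156)
  net <- ppi_network(dplyr::bind_rows(
    complete_edges(sprintf("c%d", 1:6)),
    path_edges(sprintf("b%03d", 1:200))
  ))
  st <- grow_seed(net, c("c1", "c2", "c3"), alpha = 0.5)
  expect_setequal(state_members(st), sprintf("c%d", 1:6))
})

test_that("expansion stops immediately when every gain is negative", {
  net <- two_k3_bridge()
  # neighbor d of {a,b,c} has gain -1/14 at alpha = 1
  st <- grow_seed(net, c("a", "b", "c"), alpha = 1)
  expect_setequal(state_members(st), c("a", "b", "c"))
})

test_that("a whole-network K4 grows to all four nodes at alpha = 1", {
  net <- ppi_network(complete_edges(letters[1:4]))
  st <- grow_seed(net, c("a", "b", "c"), alpha = 1)
  expect_setequal(state_members(st), letters[1:4])
  expect_error(grow_seed(net, c("a", "b", "zz"), 1), "unknown")
})

test_that("non-triangle seeds are rejected", {
  net <- ppi_network(path_edges(c("a", "b", "c", "d")))
  expect_error(grow_seed(net, c("a", "b", "c"), 0.5), "not a triangle")
})

test_that("every returned expansion carries a strict stop certificate", {
  for (seed in 1:4) {
    net <- random_network(25, 0.3, seed * 5 + 2)
    tri <- enumerate_triangles(net)
    if (nrow(tri) == 0) next
    for (k in seq_len(min(3, nrow(tri)))) {
      st <- grow_seed(net, tri[k, ], alpha = 0.4)
      nbr <- state_neighbors(st)
      if (length(nbr) == 0) next
      direct <- vapply(nbr, function(v) {
        delta_lq_alpha(net, v, state_members(st), 0.4)
      }, 0)
      expect_lt(max(direct), 0)
    }
  }
})

test_that("each greedy step adds its gain exactly, and every gain is >= 0", {
  # the merge gain is defined relative to the singleton's own score, so the
  # exact bookkeeping along the greedy path is
  #   LQ_a(S + v) = LQ_a(S) + dLQ_a(v, S) + LQ_a({v})
  # with every accepted dLQ_a(v, S) non-negative
  n_steps <- 0
  for (seed in c(77, 78, 79)) {
    net <- random_network(30, 0.35, seed)
    tri <- enumerate_triangles(net)
    for (k in seq_len(min(5, nrow(tri)))) {
      seed3 <- unlist(tri[k, c("v", "w", "x")], use.names = FALSE)
      state <- subnetwork_state(net, seed3, 1)
      score <- lq_alpha(net, state_members(state), 1)
      while (length(state$nbr) > 0 && max(state$delta) >= 0) {
        gain <- max(state$delta)
        expect_gte(gain, 0)
        best <- state_neighbors(state)[which.max(state$delta)]
        state <- update_deltas_after_merge(state, best)
        new_score <- lq_alpha(net, state_members(state), 1)
        expect_equal(new_score,
                     score + gain + lq_alpha(net, best, 1),
                     tolerance = 1e-12)
        score <- new_score
        n_steps <- n_steps + 1
      }
    }
  }
  expect_gt(n_steps, 0)
})

test_that("overlap score is intersection over the smaller set", {
  expect_equal(overlap_score(letters[1:4], letters[1:4]), 1)
  expect_equal(overlap_score(letters[1:4], letters[5:8]), 0)
  expect_equal(overlap_score(c("a", "b", "c", "d", "e"),
                             c("c", "d", "e", "f", "g", "h", "i", "j")),
               0.6)
  expect_error(overlap_score(character(0), "a"), "empty")
})

test_that("complex merging is strict, transitive and order-independent", {
  # score 0.75 merges
  m1 <- merge_complexes(list(c("a", "b", "c", "d"), c("b", "c", "d", "e")))
  expect_equal(m1, list(c("a", "b", "c", "d", "e")))
  # score exactly 0.5 does not merge
  m2 <- merge_complexes(list(c("a", "b", "c", "d"), c("c", "d", "e", "f")))
  expect_length(m2, 2)
  # disjoint inputs pass through
  m3 <- merge_complexes(list(c("a", "b"), c("c", "d")))
  expect_length(m3, 2)

  # result is independent of input order and has no remaining pair > 0.5
  sets <- list(c("a", "b", "c", "d"), c("b", "c", "d", "e"),
               c("d", "e", "f", "g"), c("x", "y", "z"),
               c("e", "f", "g", "h", "i"))
  ref <- merge_complexes(sets)
  for (perm_seed in 1:5) {
    perm <- withr::with_seed(perm_seed, sample(seq_along(sets)))
    expect_identical(merge_complexes(sets[perm]), ref)
  }
  if (length(ref) > 1) {
    for (i in seq_len(length(ref) - 1)) {
      for (j in (i + 1):length(ref)) {
        expect_lte(overlap_score(ref[[i]], ref[[j]]), 0.5)
      }
    }
  }
})

test_that("density score is connectivity times size", {
  k5 <- ppi_network(complete_edges(letters[1:5]))
  expect_equal(density_score(k5, letters[1:5]), 5)
  cyc <- ppi_network(edge_df("a", "b", "b", "c", "c", "d", "d", "a"))
  expect_equal(density_score(cyc, c("a", "b", "c", "d")), 8 / 3)
  tree <- ppi_network(path_edges(letters[1:5]))
  expect_equal(density_score(tree, letters[1:5]), 2)
  expect_error(density_score(k5, "a"), "two members")
})

test_that("the pipeline recovers two disjoint K5s beside a large tree", {
  tree_ids <- sprintf("t%02d", 1:50)
  net <- ppi_network(dplyr::bind_rows(
    complete_edges(sprintf("p%d", 1:5)),
    complete_edges(sprintf("q%d", 1:5)),
    path_edges(tree_ids)
  ))
  fit <- run_mipalm(net, alpha = 0.5, delta = 0)
  expect_equal(nrow(fit$complexes), 2)
  expect_setequal(unlist(fit$complexes$members),
                  c(sprintf("p%d", 1:5), sprintf("q%d", 1:5)))
  # a threshold above any possible density score empties the result
  fit_hi <- run_mipalm(net, alpha = 0.5, delta = 60)
  expect_equal(nrow(fit_hi$complexes), 0)
})

test_that("a triangle-free network yields an empty result with a warning", {
  net <- ppi_network(path_edges(letters[1:6]))
  expect_warning(fit <- run_mipalm(net, alpha = 0.5, delta = 0),
                 "no triangles")
  expect_equal(nrow(fit$complexes), 0)
})

test_that("pipeline output honors its contract and is reproducible", {
  sim <- generate_synthetic(synthetic_spec(n_complexes = 6,
                                           background_nodes = 80,
                                           background_edge_prob = 0.01,
                                           seed = 5))
  fit <- run_mipalm(sim$network, alpha = 0.5, delta = 1.5)
  sets <- fit$complexes$members
  # no output pair overlaps by more than 0.5
  if (length(sets) > 1) {
    for (i in seq_len(length(sets) - 1)) {
      for (j in (i + 1):length(sets)) {
        expect_lte(overlap_score(sets[[i]], sets[[j]]), 0.5)
      }
    }
  }
  # all results clear the density threshold and the size-3 discard
  expect_true(all(fit$complexes$density_score >= 1.5))
  expect_true(all(fit$complexes$size > 3))
  # density scores recompute from the network
  for (k in seq_along(sets)) {
    expect_equal(fit$complexes$density_score[k],
                 density_score(sim$network, sets[[k]]))
  }
  # bit-identical repeat
  fit2 <- run_mipalm(sim$network, alpha = 0.5, delta = 1.5)
  expect_identical(fit$complexes, fit2$complexes)
})

test_that("parameter tuning returns a grid argmax with smallest-first ties", {
  sim <- generate_synthetic(synthetic_spec(n_complexes = 4,
                                           size_range = c(5, 6),
                                           background_nodes = 30,
                                           background_edge_prob = 0.01,
                                           attachment_edges = 1,
                                           seed = 9))
  tun <- tune_mipalm(sim$network, sim$gold)
  # the tuned F is attained by rerunning the pipeline at (alpha, delta)
  fit <- suppressWarnings(run_mipalm(sim$network, tun$alpha, tun$delta))
  expect_equal(evaluate_complexes(fit, sim$gold)$f_measure, tun$f_measure)
  # no coarse grid point beats the returned optimum
  coarse <- tun$alpha_trace[tun$alpha_trace$stage == "coarse", ]
  expect_gte(tun$f_measure, max(coarse$f_measure))
  expect_gte(tun$f_measure, max(tun$delta_trace$f_measure))

  # constant objective falls back to the smallest grid values
  gold_far <- list(c("zz1", "zz2", "zz3", "zz4"))
  tun0 <- tune_mipalm(sim$network, gold_far)
  expect_equal(tun0$alpha, 0)
  expect_equal(tun0$delta, 0)
  expect_equal(tun0$f_measure, 0)
  expect_error(tune_mipalm(sim$network, list()), "empty")
})
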