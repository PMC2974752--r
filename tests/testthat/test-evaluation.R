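test_that("matching score is c^2/(a*b)", {
  expect_equal(matching_score(letters[1:5], letters[1:5]), 1)
  expect_equal(matching_score(letters[1:5], letters[10:14]), 0)
  pred <- sprintf("p%02d", 1:10)
  known <- c(pred[1:4], sprintf("k%d", 1:2))
  expect_equal(matching_score(pred, known), 16 / 60)
  expect_error(matching_score(character(0), "a"), "empty")
})

test_that("matching score is bounded and equals 1 only for identical sets", {
  for (seed in 1:20) {
    sets <- withr::with_seed(seed, {
      list(sample(letters, sample(3:10, 1)), sample(letters, sample(3:10, 1)))
    })
    s <- matching_score(sets[[1]], sets[[2]])
    expect_gte(s, 0)
    expect_lte(s, 1)
    if (s == 1) expect_setequal(sets[[1]], sets[[2]])
  }
})

test_that("precision, recall and F-measure count matched entities", {
  gold <- list(letters[1:5], letters[6:10], letters[11:15])
  # identical predictions: everything matches
  ev <- evaluate_complexes(gold, gold)
  expect_equal(c(ev$precision, ev$recall, ev$f_measure), c(1, 1, 1))
  # disjoint predictions: nothing matches
  ev0 <- evaluate_complexes(list(c("x1", "x2", "x3")), gold)
  expect_equal(c(ev0$precision, ev0$recall, ev0$f_measure), c(0, 0, 0))
  # 2 predictions, 3 gold, exactly one match
  ev1 <- evaluate_complexes(list(letters[1:5], c("y1", "y2", "y3")), gold)
  expect_equal(ev1$precision, 1 / 2)
  expect_equal(ev1$recall, 1 / 3)
  expect_equal(ev1$f_measure, 0.4)
  # no predictions: precision 0 by convention
  evn <- evaluate_complexes(list(), gold)
  expect_equal(evn$precision, 0)
  expect_equal(evn$f_measure, 0)
  expect_error(evaluate_complexes(gold, list()), "empty")
  expect_error(evaluate_complexes(gold, gold, threshold = 0), "threshold")
})

test_that("evaluation is monotone in the prediction list", {
  gold <- list(letters[1:5], letters[6:10])
  base <- list(letters[1:5])
  with_extra <- c(base, list(c("z1", "z2", "z3")))
  # adding a prediction never decreases recall
  expect_gte(evaluate_complexes(with_extra, gold)$recall,
             evaluate_complexes(base, gold)$recall)
  # removing an unmatched prediction never decreases precision
  expect_gte(evaluate_complexes(base, gold)$precision,
             evaluate_complexes(with_extra, gold)$precision)
})

test_that("hypergeometric enrichment matches exact tail sums", {
  # N = 20, K = n = x = 3 has closed form 1/C(20,3)
  bg <- sprintf("p%02d", 1:20)
  ann <- tibble::tibble(protein = bg[1:3], label = "T")
  res <- go_enrichment(bg[1:3], ann, background = bg)
  expect_equal(res$p_value, 1 / 1140, tolerance = 1e-12)

  # a term carried by every background protein has p = 1
  ann_all <- tibble::tibble(protein = bg, label = "ubiquitous")
  expect_equal(go_enrichment(bg[1:5], ann_all, background = bg)$p_value, 1)

  # brute-force tail sums on random instances (N <= 30)
  for (seed in 1:10) {
    cfg <- withr::with_seed(seed, {
      N <- sample(10:30, 1)
      K <- sample(2:(N - 1), 1)
      n <- sample(2:(N - 1), 1)
      list(N = N, K = K, n = n)
    })
    bg <- sprintf("q%02d", seq_len(cfg$N))
    ann <- tibble::tibble(protein = bg[seq_len(cfg$K)], label = "T")
    members <- withr::with_seed(seed + 99, sample(bg, cfg$n))
    res <- go_enrichment(members, ann, background = bg)
    x <- length(intersect(members, bg[seq_len(cfg$K)]))
    if (x == 0) {
      expect_equal(nrow(res), 0)
    } else {
      expect_equal(res$p_value,
                   brute_hyper_tail(x, cfg$K, cfg$N, cfg$n),
                   tolerance = 1e-12)
    }
  }
})

test_that("Bonferroni correction multiplies by terms tested, capped at 1", {
  bg <- sprintf("p%02d", 1:20)
  # ten labels, each carried by the first three proteins
  ann <- tidyr::expand_grid(protein = bg[1:3],
                            label = sprintf("T%02d", 1:10))
  res <- go_enrichment(bg[1:3], ann, background = bg)
  expect_equal(nrow(res), 10)
  expect_equal(res$p_bonferroni, pmin(1, res$p_value * 10))
  # weak raw p-values cap at 1 after correction
  ann2 <- dplyr::bind_rows(
    tidyr::expand_grid(protein = bg, label = sprintf("U%02d", 1:10)),
    tibble::tibble(protein = bg[1], label = "rare")
  )
  res2 <- go_enrichment(bg[1:5], ann2, background = bg)
  expect_true(all(res2$p_bonferroni <= 1))
  expect_true(any(res2$p_bonferroni == 1))
})

test_that("co-localization log-odds follows the connectivity model", {
  # clique with all members in one compartment: observed = expected, not localized
  k4 <- ppi_network(complete_edges(letters[1:4]))
  ann <- tibble::tibble(protein = letters[1:4], label = "nucleus")
  res <- colocalization_log_odds(k4, letters[1:4], ann)
  expect_equal(res$log_odds, 0)
  expect_false(res$localized)

  # 4-path with two co-localized endpoints of one edge: log(2)
  p4 <- ppi_network(path_edges(c("a", "b", "c", "d")))
  ann2 <- tibble::tibble(protein = c("a", "b"), label = "vacuole")
  res2 <- colocalization_log_odds(p4, c("a", "b", "c", "d"), ann2)
  expect_equal(res2$log_odds, log(2))
  expect_true(res2$localized)

  # compartments without two annotated members give the NA sentinel
  ann3 <- tibble::tibble(protein = "a", label = "mito")
  res3 <- colocalization_log_odds(p4, c("a", "b", "c", "d"), ann3,
                                  compartments = c("mito", "er"))
  expect_true(all(is.na(res3$log_odds)))
  expect_true(all(!res3$localized))

  # a complex with no internal edges is an error
  net <- ppi_network(edge_df("a", "b", "c", "d"))
  expect_error(colocalization_log_odds(net, c("a", "c"), ann2),
               "no internal edges")
})

test_that("co-localization score is invariant under protein relabeling", {
  net <- random_network(12, 0.5, 42)
  ids <- network_nodes(net)
  members <- ids[1:6]
  ann <- tibble::tibble(protein = members[1:4], label = "golgi")
  base <- colocalization_log_odds(net, members, ann)

  relabel <- stats::setNames(sprintf("z%02d", seq_along(ids)), ids)
  edges <- network_edges(net)
  net2 <- ppi_network(tibble::tibble(from = unname(relabel[edges$from]),
                                     to = unname(relabel[edges$to])))
  ann2 <- tibble::tibble(protein = unname(relabel[ann$protein]),
                         label = "golgi")
  re <- colocalization_log_odds(net2, unname(relabel[members]), ann2)
  expect_equal(re$log_odds, base$log_odds)
  expect_equal(re$n_edges, base$n_edges)
})
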