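#' Matching score between a predicted and a known complex
#'
#' \deqn{\omega = c^2 / (a \cdot b)} with `a`, `b` the sizes of the two
#' sets and `c` the size of their intersection. A prediction is counted as
#' matching a known complex when \eqn{\omega \ge 0.2} (the conventional
#' threshold).
#'
#' @param pred,known Non-empty character vectors of protein IDs.
#' @return A score in `[0, 1]`, equal to 1 only when the sets coincide.
#' @export
matching_score <- function(pred, known) {
  pred <- unique(pred)
  known <- unique(known)
  if (length(pred) == 0L || length(known) == 0L) {
    rlang::abort("matching score of an empty set is undefined")
  }
  length(intersect(pred, known))^2 / (length(pred) * length(known))
}

#' Precision, recall and F-measure against a gold standard
#'
#' A prediction is matched if its matching score against at least one known
#' complex reaches `threshold`; a known complex is matched if at least one
#' prediction reaches `threshold` against it. Precision is the fraction of
#' predictions matched, recall the fraction of known complexes matched, and
#' the F-measure their harmonic mean (0 when both are 0). A prediction may
#' match several known complexes and vice versa; matched entities, not
#' matched pairs, are counted.
#'
#' @param preds A `mipalm_fit`, catalog tibble, or list of member vectors.
#' @param gold A non-empty complex catalog or list of member vectors.
#' @param threshold Matching-score cutoff in `(0, 1]` (default 0.2).
#' @return An object of class `complex_evaluation` with fields `precision`,
#'   `recall`, `f_measure`, `threshold`, `n_pred`, `n_known`, and tibbles
#'   `prediction_matches` (per prediction: best partner and score) and
#'   `known_matches`. Supports `tidy()` and `glance()`.
#' @export
evaluate_complexes <- function(preds, gold, threshold = 0.2) {
  pred_sets <- complex_members(preds)
  gold_sets <- complex_members(gold)
  if (length(gold_sets) == 0L) {
    rlang::abort("gold-standard catalog is empty")
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    rlang::abort("`threshold` must lie in (0, 1]")
  }
  n_pred <- length(pred_sets)
  n_known <- length(gold_sets)

  if (n_pred > 0L) {
    omega <- matrix(0, n_pred, n_known)
    for (i in seq_len(n_pred)) {
      for (j in seq_len(n_known)) {
        omega[i, j] <- matching_score(pred_sets[[i]], gold_sets[[j]])
      }
    }
    best_j <- apply(omega, 1L, which.max)
    pm <- tibble::tibble(
      prediction = seq_len(n_pred),
      size = lengths(pred_sets),
      best_known = best_j,
      best_score = omega[cbind(seq_len(n_pred), best_j)],
      matched = apply(omega, 1L, max) >= threshold
    )
    best_i <- apply(omega, 2L, which.max)
    km <- tibble::tibble(
      known = seq_len(n_known),
      size = lengths(gold_sets),
      best_prediction = best_i,
      best_score = omega[cbind(best_i, seq_len(n_known))],
      matched = apply(omega, 2L, max) >= threshold
    )
    precision <- mean(pm$matched)
    recall <- mean(km$matched)
  } else {
    pm <- tibble::tibble(prediction = integer(), size = integer(),
                         best_known = integer(), best_score = double(),
                         matched = logical())
    km <- tibble::tibble(known = seq_len(n_known), size = lengths(gold_sets),
                         best_prediction = NA_integer_,
                         best_score = 0, matched = FALSE)
    precision <- 0
    recall <- 0
  }
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  structure(
    list(precision = precision, recall = recall, f_measure = f,
         threshold = threshold, n_pred = n_pred, n_known = n_known,
         prediction_matches = pm, known_matches = km),
    class = "complex_evaluation"
  )
}

#' @export
print.complex_evaluation <- function(x, ...) {
  cat(sprintf(
    "complex evaluation (omega >= %g): precision %.3f, recall %.3f, F %.3f\n",
    x$threshold, x$precision, x$recall, x$f_measure))
  cat(sprintf("  %d predictions vs %d known complexes\n",
              x$n_pred, x$n_known))
  invisible(x)
}

#' Hypergeometric term-enrichment test for one complex
#'
#' For every label carried by at least one complex member, computes the
#' upper-tail hypergeometric probability of observing at least the seen
#' number of annotated members: population `N` = background proteins,
#' successes `K` = background proteins carrying the label, draws `n` =
#' annotated complex members, observed `x`. P-values are
#' Bonferroni-corrected by the number of labels tested for this complex
#' (capped at 1); a complex is conventionally called enriched when any
#' corrected p-value is at most 0.05.
#'
#' @param members Character vector of complex member IDs.
#' @param annotations An annotation table (columns `protein`, `label`).
#' @param background Character vector of background proteins; defaults to
#'   every annotated protein. Complex members outside the background count
#'   as unannotated and are excluded from the draw.
#' @return A tibble with columns `label`, `x`, `n`, `K`, `N`, `p_value`,
#'   `p_bonferroni`, sorted by `p_value`.
#' @export
go_enrichment <- function(members, annotations, background = NULL) {
  ann <- as_annotation(annotations)
  if (is.null(background)) background <- unique(ann$protein)
  background <- unique(background)
  ann <- ann[ann$protein %in% background, , drop = FALSE]
  members <- intersect(unique(members), background)
  n <- length(members)
  N <- length(background)
  if (n > N) rlang::abort("complex larger than background")
  hit <- ann[ann$protein %in% members, , drop = FALSE]
  labels <- sort(unique(hit$label))
  if (length(labels) == 0L) {
    return(tibble::tibble(label = character(), x = integer(), n = integer(),
                          K = integer(), N = integer(), p_value = double(),
                          p_bonferroni = double()))
  }
  x <- vapply(labels, function(l) length(unique(hit$protein[hit$label == l])),
              0L, USE.NAMES = FALSE)
  K <- vapply(labels, function(l) length(unique(ann$protein[ann$label == l])),
              0L, USE.NAMES = FALSE)
  if (any(x > K)) rlang::abort("inconsistent annotations: x > K")
  p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
  out <- tibble::tibble(label = labels, x = x, n = n, K = K, N = N,
                        p_value = p,
                        p_bonferroni = pmin(1, p * length(labels)))
  out[order(out$p_value, out$label), , drop = FALSE]
}

#' Co-localization log-odds of a complex
#'
#' Compares, per sub-cellular compartment `k`, the observed number of
#' intra-complex edges whose two endpoints are both annotated to `k`
#' (`m_sk`) with its expectation under the complex's own connectivity
#' \eqn{p_s = 2 m_{ss} / (n_s (n_s - 1))}:
#' \deqn{\bar m_{sk} = \frac{n_{sk}(n_{sk}-1)}{2} \, p_s, \qquad
#'   \mathrm{score} = \log(m_{sk} / \bar m_{sk})}
#' The complex is called localized to `k` when the score is strictly
#' positive. Compartments with fewer than two annotated members or no
#' co-localized edge get an `NA` score and are reported as not localized.
#' Multi-compartment proteins count toward every compartment they carry.
#'
#' @param net A [ppi_network].
#' @param members Character vector of at least two member IDs with at least
#'   one intra-complex edge.
#' @param annotations An annotation table of protein-compartment pairs.
#' @param compartments Optional character vector restricting the
#'   compartments scored; defaults to every compartment carried by a
#'   member.
#' @return A tibble with columns `compartment`, `n_members` (`n_sk`),
#'   `n_edges` (`m_sk`), `expected`, `log_odds`, `localized`.
#' @export
colocalization_log_odds <- function(net, members, annotations,
                                    compartments = NULL) {
  stopifnot(inherits(net, "ppi_network"))
  ann <- as_annotation(annotations)
  members <- unique(as.character(members))
  n_s <- length(members)
  if (n_s < 2L) rlang::abort("complex must have at least two members")
  idx <- node_index(net, members)
  m_ss <- intra_edge_count(net, idx)
  if (m_ss == 0L) {
    rlang::abort("complex has no internal edges: connectivity undefined")
  }
  p_s <- 2 * m_ss / (n_s * (n_s - 1))

  ann <- ann[ann$protein %in% members, , drop = FALSE]
  if (is.null(compartments)) compartments <- sort(unique(ann$label))
  if (length(compartments) == 0L) {
    return(tibble::tibble(compartment = character(), n_members = integer(),
                          n_edges = integer(), expected = double(),
                          log_odds = double(), localized = logical()))
  }

  flag <- logical(length(net$nodes))
  flag[idx] <- TRUE
  rows <- lapply(compartments, function(k) {
    loc <- unique(ann$protein[ann$label == k])
    n_sk <- length(loc)
    loc_idx <- match(loc, net$nodes)
    m_sk <- if (n_sk >= 2L) {
      lf <- logical(length(net$nodes))
      lf[loc_idx] <- TRUE
      sum(vapply(loc_idx, function(v) sum(lf[net$adj[[v]]]), 0L)) %/% 2L
    } else {
      0L
    }
    expected <- n_sk * (n_sk - 1) / 2 * p_s
    lo <- if (n_sk >= 2L && m_sk > 0L) log(m_sk / expected) else NA_real_
    tibble::tibble(compartment = k, n_members = n_sk,
                   n_edges = as.integer(m_sk), expected = expected,
                   log_odds = lo,
                   localized = !is.na(lo) && lo > 0)
  })
  dplyr::bind_rows(rows)
}
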