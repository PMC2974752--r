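#' Specification for a synthetic planted-complex benchmark
#'
#' Describes a sparse Erdos-Renyi background network with embedded dense
#' sub-networks ("planted complexes") of realistic protein-complex size
#' (the defaults plant cliques of 6-10 members, in line with known
#' complexes whose median size is below 10). Used by
#' [generate_synthetic()] to produce a network, a ground-truth catalog and
#' a synthetic annotation table, so the whole pipeline is testable without
#' external downloads.
#'
#' @param n_complexes Number of planted complexes.
#' @param size_range Length-2 integer vector of (min, max) member counts;
#'   minimum at least 4 so planted complexes survive the size-3 discard.
#' @param intra_density Probability of each within-complex edge; must
#'   exceed `background_edge_prob`. 1 plants cliques.
#' @param background_nodes Number of background proteins.
#' @param background_edge_prob Erdos-Renyi edge probability of the
#'   background.
#' @param overlap_fraction Fraction of complexes sharing one member with
#'   the previously planted complex.
#' @param attachment_edges Random complex-to-background edges per complex.
#' @param n_noise_labels Size of the pool of uninformative annotation
#'   labels added on top of the per-complex labels.
#' @param seed RNG seed; the same seed gives bit-identical output.
#' @return An object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n_complexes = 20,
                           size_range = c(6, 10),
                           intra_density = 1,
                           background_nodes = 500,
                           background_edge_prob = 0.005,
                           overlap_fraction = 0,
                           attachment_edges = 2,
                           n_noise_labels = 10,
                           seed = 1) {
  spec <- list(n_complexes = as.integer(n_complexes),
               size_range = as.integer(size_range),
               intra_density = intra_density,
               background_nodes = as.integer(background_nodes),
               background_edge_prob = background_edge_prob,
               overlap_fraction = overlap_fraction,
               attachment_edges = as.integer(attachment_edges),
               n_noise_labels = as.integer(n_noise_labels),
               seed = as.integer(seed))
  if (spec$intra_density <= spec$background_edge_prob) {
    rlang::abort("`intra_density` must exceed `background_edge_prob`")
  }
  if (length(spec$size_range) != 2L || spec$size_range[1] < 4L ||
      spec$size_range[2] < spec$size_range[1]) {
    rlang::abort("`size_range` must be (min, max) with min >= 4")
  }
  if (spec$n_complexes < 1L) rlang::abort("need at least one complex")
  if (spec$intra_density > 1 || spec$intra_density <= 0) {
    rlang::abort("`intra_density` must lie in (0, 1]")
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic benchmark network with planted complexes
#'
#' Plants each complex as a dense Erdos-Renyi subgraph (re-drawn until it
#' is connected and contains at least one triangle, without which it could
#' never be seeded), overlays a sparse Erdos-Renyi background, and wires
#' each complex to the background with a few random attachment edges.
#' Every planted complex also receives a private annotation label on its
#' members; each protein additionally gets one uniform noise label, so the
#' annotation table exercises enrichment and co-localization scoring.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `network` (a [ppi_network]), `edges`
#'   (tibble), `gold` (complex catalog tibble), `annotations` (tibble with
#'   `protein`, `label`), and `spec`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "synthetic_spec")) {
    rlang::abort("`spec` must be created with synthetic_spec()")
  }
  withr::with_seed(spec$seed, generate_synthetic_impl(spec))
}

generate_synthetic_impl <- function(spec) {
  sizes <- sample(seq(spec$size_range[1], spec$size_range[2]),
                  spec$n_complexes, replace = TRUE)
  members <- vector("list", spec$n_complexes)
  next_id <- 1L
  new_ids <- function(k) {
    ids <- sprintf("P%04d", next_id + seq_len(k) - 1L)
    next_id <<- next_id + k
    ids
  }
  for (i in seq_len(spec$n_complexes)) {
    shared <- character(0)
    if (i > 1L && spec$overlap_fraction > 0 &&
        stats::runif(1) < spec$overlap_fraction) {
      shared <- sample(members[[i - 1L]], 1L)
    }
    members[[i]] <- c(shared, new_ids(sizes[i] - length(shared)))
  }

  planted_edges <- lapply(members, function(mem) {
    draw_dense_subgraph(mem, spec$intra_density)
  })

  bg_nodes <- sprintf("B%04d", seq_len(spec$background_nodes))
  bg_edges <- draw_er_edges(bg_nodes, spec$background_edge_prob)

  attach_edges <- NULL
  if (spec$attachment_edges > 0L && spec$background_nodes > 0L) {
    attach_edges <- dplyr::bind_rows(lapply(members, function(mem) {
      tibble::tibble(
        from = sample(mem, spec$attachment_edges, replace = TRUE),
        to = sample(bg_nodes, spec$attachment_edges, replace = TRUE)
      )
    }))
  }

  edges <- dplyr::bind_rows(c(planted_edges, list(bg_edges, attach_edges)))
  net <- ppi_network(edges, quiet = TRUE)

  gold <- tibble::tibble(
    complex = sprintf("C%02d", seq_along(members)),
    size = lengths(members),
    members = lapply(members, sort)
  )

  complex_ann <- dplyr::bind_rows(lapply(seq_along(members), function(i) {
    tibble::tibble(protein = members[[i]],
                   label = sprintf("K%02d", i))
  }))
  all_proteins <- net$nodes
  noise_ann <- tibble::tibble(
    protein = all_proteins,
    label = sample(sprintf("N%02d", seq_len(spec$n_noise_labels)),
                   length(all_proteins), replace = TRUE)
  )
  annotations <- dplyr::distinct(dplyr::bind_rows(complex_ann, noise_ann))

  list(network = net,
       edges = network_edges(net),
       gold = gold,
       annotations = annotations,
       spec = spec)
}

# all unordered pairs of `nodes` kept independently with probability p
draw_er_edges <- function(nodes, p) {
  n <- length(nodes)
  if (n < 2L || p <= 0) {
    return(tibble::tibble(from = character(), to = character()))
  }
  pairs <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  tibble::tibble(from = nodes[pairs[1L, keep]],
                 to = nodes[pairs[2L, keep]])
}

# dense subgraph on `mem`, re-drawn until connected with >= 1 triangle
draw_dense_subgraph <- function(mem, p) {
  repeat {
    e <- draw_er_edges(mem, p)
    if (nrow(e) < length(mem) - 1L) next
    if (!edges_connected(mem, e)) next
    if (!edges_have_triangle(mem, e)) next
    return(e)
  }
}

edges_connected <- function(mem, e) {
  comp <- stats::setNames(seq_along(mem), mem)
  for (k in seq_len(nrow(e))) {
    a <- comp[[e$from[k]]]
    b <- comp[[e$to[k]]]
    if (a != b) comp[comp == b] <- a
  }
  length(unique(comp)) == 1L
}

edges_have_triangle <- function(mem, e) {
  if (nrow(e) < 3L) return(FALSE)
  adj <- lapply(stats::setNames(seq_along(mem), mem), function(i) character(0))
  for (k in seq_len(nrow(e))) {
    adj[[e$from[k]]] <- c(adj[[e$from[k]]], e$to[k])
    adj[[e$to[k]]] <- c(adj[[e$to[k]]], e$from[k])
  }
  for (k in seq_len(nrow(e))) {
    if (length(intersect(adj[[e$from[k]]], adj[[e$to[k]]])) > 0L) {
      return(TRUE)
    }
  }
  FALSE
}
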