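#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a miPALM fit into its complex table
#'
#' @param x A `mipalm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per predicted complex (`complex`, `size`,
#'   `n_edges`, `density_score`, `members`).
#' @method tidy mipalm_fit
#' @export
tidy.mipalm_fit <- function(x, ...) {
  x$complexes
}

#' One-row summary of a miPALM fit
#'
#' @param x A `mipalm_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the parameters and per-stage counts.
#' @method glance mipalm_fit
#' @export
glance.mipalm_fit <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha,
    delta = x$delta,
    n_seeds = x$stats$n_seeds,
    n_grown = x$stats$n_grown,
    n_candidates = x$stats$n_candidates,
    n_after_merge = x$stats$n_after_merge,
    n_complexes = nrow(x$complexes),
    median_size = if (nrow(x$complexes)) {
      stats::median(x$complexes$size)
    } else {
      NA_real_
    }
  )
}

#' Tidy an evaluation into per-prediction match rows
#'
#' @param x A `complex_evaluation`.
#' @param ... Unused.
#' @return The per-prediction tibble of best matches.
#' @method tidy complex_evaluation
#' @export
tidy.complex_evaluation <- function(x, ...) {
  x$prediction_matches
}

#' One-row summary of an evaluation
#'
#' @param x A `complex_evaluation`.
#' @param ... Unused.
#' @return A one-row tibble with precision, recall, F-measure and counts.
#' @method glance complex_evaluation
#' @export
glance.complex_evaluation <- function(x, ...) {
  tibble::tibble(
    precision = x$precision,
    recall = x$recall,
    f_measure = x$f_measure,
    threshold = x$threshold,
    n_pred = x$n_pred,
    n_known = x$n_known
  )
}

#' Tidy a tuning result
#'
#' @param x A `mipalm_tuning`.
#' @param ... Unused.
#' @return The combined grid traces as one tibble with a `parameter`
#'   column.
#' @method tidy mipalm_tuning
#' @export
tidy.mipalm_tuning <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(x$alpha_trace, value = "alpha"),
                  parameter = "alpha"),
    dplyr::mutate(dplyr::rename(x$delta_trace, value = "delta"),
                  parameter = "delta", stage = "delta")
  )
}

#' @rdname tidy.mipalm_tuning
#' @method glance mipalm_tuning
#' @export
glance.mipalm_tuning <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, delta = x$delta, f_measure = x$f_measure)
}
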