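#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot predicted complex sizes against density scores
#'
#' @param object A `mipalm_fit`.
#' @param ... Unused.
#' @return A ggplot: one point per predicted complex, size vs density
#'   score, with the filter threshold `delta` drawn as a dashed line.
#' @method autoplot mipalm_fit
#' @export
autoplot.mipalm_fit <- function(object, ...) {
  dat <- object$complexes
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = .data$size, y = .data$density_score)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$delta, linetype = "dashed") +
    ggplot2::labs(x = "complex size (proteins)",
                  y = "density score",
                  title = sprintf("miPALM complexes (alpha = %g, delta = %g)",
                                  object$alpha, object$delta))
}

#' Plot per-prediction best matching scores
#'
#' @param object A `complex_evaluation`.
#' @param ... Unused.
#' @return A ggplot histogram of best matching scores with the matching
#'   threshold drawn as a dashed line.
#' @method autoplot complex_evaluation
#' @export
autoplot.complex_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$prediction_matches,
                  ggplot2::aes(x = .data$best_score)) +
    ggplot2::geom_histogram(bins = 20, boundary = 0) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "best matching score (omega)",
                  y = "predictions",
                  title = sprintf("precision %.2f, recall %.2f, F %.2f",
                                  object$precision, object$recall,
                                  object$f_measure))
}

#' Plot tuning grid traces
#'
#' @param object A `mipalm_tuning`.
#' @param ... Unused.
#' @return A ggplot of F-measure against each parameter grid, faceted by
#'   parameter.
#' @method autoplot mipalm_tuning
#' @export
autoplot.mipalm_tuning <- function(object, ...) {
  dat <- tidy.mipalm_tuning(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$value,
                                    y = .data$f_measure)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = "parameter value", y = "F-measure")
}

#' @importFrom rlang .data
NULL
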