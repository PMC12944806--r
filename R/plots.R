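# ggplot2 views of the pipeline's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot sorted similarity-score curves per method
#'
#' One curve per method: scores divided by the method's maximum, plotted
#' against rank. A long flat tail at zero is the signature of overlap-only
#' measures; query expansion removes it.
#'
#' @param object A `phen_scores` tibble.
#' @param log_x Log-scale the rank axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phen_scores
#' @export
autoplot.phen_scores <- function(object, log_x = FALSE, ...) {
  d <- object |>
    dplyr::group_by(.data$method) |>
    dplyr::arrange(dplyr::desc(.data$score), .by_group = TRUE) |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      norm = if (max(.data$score) > 0) .data$score / max(.data$score)
             else .data$score
    ) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$rank, .data$norm,
                                       colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "rank", y = "score / max score", colour = NULL) +
    ggplot2::theme_minimal()
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Heatmap of a weighted-tau matrix
#'
#' @param object A `phen_tau` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phen_tau
#' @export
autoplot.phen_tau <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$method_a, .data$method_b,
                                  fill = .data$tau)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$tau)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "weighted tau") +
    ggplot2::theme_minimal()
}

#' Bar chart of the top consensus diseases
#'
#' @param object A `phen_consensus` tibble.
#' @param top Number of diseases shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phen_consensus
#' @export
autoplot.phen_consensus <- function(object, top = 20, ...) {
  d <- object[order(object$rank), ][seq_len(min(top, nrow(object))), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$score,
                                  stats::reorder(.data$disease_id,
                                                 .data$score))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "normalised aggregate score", y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of disease categories among the top-ranked diseases
#'
#' @param object A `phen_categories` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phen_categories
#' @export
autoplot.phen_categories <- function(object, ...) {
  d <- object[object$count > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$count,
                                  stats::reorder(.data$category_name,
                                                 .data$count))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = sprintf("diseases among top %d",
                              attr(object, "k") %||% NA),
                  y = NULL) +
    ggplot2::theme_minimal()
}
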