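#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an HBS classification
#'
#' Degree versus betweenness (square-root scale) for every node, point size
#' mapped to eigenvector centrality and colour to the HBS label; dashed lines
#' mark the two mean thresholds.
#'
#' @param object An `hbs_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hbs_result
#' @export
autoplot.hbs_result <- function(object, ...) {
  thr <- attr(object, "thresholds", exact = TRUE)
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$degree, y = .data$betweenness,
                               size = .data$eigenvector, colour = .data$is_hbs)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = thr$degree, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = thr$betweenness, linetype = "dashed") +
    ggplot2::scale_y_sqrt() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "degree", y = "betweenness", colour = "HBS",
                  size = "eigenvector",
                  title = "Hub-bottleneck-switch classification") +
    ggplot2::theme_minimal()
}

#' Plot an enrichment result
#'
#' Horizontal bars of -log10(q) for the top terms, coloured by significance.
#'
#' @param object An `enrichment_result`.
#' @param n_terms Number of top terms to show (default 15).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, n_terms = 15, ...) {
  df <- head(as_tibble(object), n_terms)
  df$label <- ifelse(is.na(df$name), df$term_id, df$name)
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$q),
                                   y = stats::reorder(.data$label, -.data$q),
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10](q)), y = NULL,
                  title = "Term over-representation") +
    ggplot2::theme_minimal()
}

#' Plot CNA call counts per sample and condition
#'
#' @param call_counts Tibble from [count_cna_calls()].
#' @return A ggplot.
#' @export
plot_cna_calls <- function(call_counts) {
  ggplot2::ggplot(call_counts,
                  ggplot2::aes(x = .data$sample_id, y = .data$n_calls,
                               fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "CNA calls", fill = "condition",
                  title = "Significant CNA calls") +
    ggplot2::theme_minimal()
}
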