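# ggplot2 views of the main result types: confusion matrix, feature
# block structure, enrichment screen and protocol metrics.

#' @describeIn evaluate_predictions autoplot() draws the confusion matrix
#'   as a count heatmap (rows = predicted, columns = annotated).
#' @param object the object to plot.
#' @export
autoplot.stage_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("predicted", "annotated", "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$annotated, .data$predicted,
                                   fill = .data$count)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(
      x = "Annotated stage", y = "Predicted stage",
      title = sprintf("Accuracy %.3f, kappa %.3f", object$accuracy,
                      object$kappa)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-stage block structure of a feature matrix
#'
#' Shows, per sample and per stage-network block, the fraction of edges
#' retained (non-zero entries). Samples from a stage should retain most
#' edges in their own stage's block.
#'
#' @param features feature tibble from [build_feature_matrix()] (needs
#'   its `"layout"` attribute).
#' @param truth optional tibble with `sample_id`, `stage` used to facet
#'   samples by annotated stage.
#' @return a ggplot object.
#' @export
plot_feature_blocks <- function(features, truth = NULL) {
  layout <- attr(features, "layout", exact = TRUE)
  if (is.null(layout)) {
    abort("`features` lacks a layout attribute; build it with build_feature_matrix().")
  }
  long <- tidyr::pivot_longer(features, -"sample_id",
                              names_to = "position_id", values_to = "value")
  long$network_stage <- layout$stage[match(long$position_id,
                                           sprintf("p%04d", layout$position))]
  df <- long |>
    dplyr::group_by(.data$sample_id, .data$network_stage) |>
    dplyr::summarise(retained = mean(.data$value != 0), .groups = "drop")
  if (!is.null(truth)) {
    df$annotated <- as.character(truth$stage[match(df$sample_id, truth$sample_id)])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$network_stage, .data$retained)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "Stage network block", y = "Fraction of edges retained") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    p <- p + ggplot2::facet_wrap(~annotated,
                                 labeller = ggplot2::label_both)
  }
  p
}

#' Plot a pair-enrichment screen
#'
#' Bar chart of `-log10(adjusted p)` for the top pathways of an
#' [enrich_all()] result.
#'
#' @param results tibble from [enrich_all()].
#' @param top number of pathways to show (by adjusted p).
#' @return a ggplot object.
#' @export
plot_enrichment <- function(results, top = 20) {
  df <- dplyr::slice_min(results, .data$adjusted_p, n = top, with_ties = FALSE)
  df$pathway_id <- stats::reorder(df$pathway_id, -df$adjusted_p)
  ggplot2::ggplot(df, ggplot2::aes(.data$pathway_id,
                                   -log10(.data$adjusted_p),
                                   fill = .data$enriched)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ "adjusted p")) +
    ggplot2::theme_minimal()
}

#' @describeIn run_protocol autoplot() shows per-iteration accuracy and
#'   kappa.
#' @param object the object to plot.
#' @export
autoplot.stage_protocol <- function(object, ...) {
  df <- object$iteration_metrics
  df <- df[df$metric %in% c("accuracy", "kappa"), ]
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$iteration), .data$value,
                                   group = .data$metric,
                                   color = .data$metric)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Protocol iteration", y = "Metric value",
                  color = NULL) +
    ggplot2::theme_minimal()
}
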