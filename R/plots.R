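#' Plot the training loss of a GloVe model
#'
#' @param object A [train_glove()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot glove_model
#' @export
autoplot.glove_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "epoch", y = "objective",
                  title = "GloVe training loss") +
    ggplot2::theme_minimal()
}

#' Scatter ASVs on two embedding properties
#'
#' @param object An [asv_embedding()].
#' @param dims Two property columns to plot.
#' @param color Optional per-ASV grouping (e.g. block assignment or genus),
#'   named by ASV ID or in row order.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot asv_embedding
#' @export
autoplot.asv_embedding <- function(object, dims = c(1, 2), color = NULL, ...) {
  v <- unclass(object)
  df <- tibble::tibble(
    asv_id = rownames(v), x = v[, dims[1]], y = v[, dims[2]]
  )
  if (!is.null(color)) {
    df$group <- if (!is.null(names(color))) color[df$asv_id] else color
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                          color = factor(.data$group)))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  }
  p + ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = colnames(v)[dims[1]], y = colnames(v)[dims[2]],
                  color = "group") +
    ggplot2::theme_minimal()
}

#' Heatmap of property-pathway correlations
#'
#' @param object A [max_correlation_permutation_test()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pathway_correlation
#' @export
autoplot.pathway_correlation <- function(object, ...) {
  df <- tibble::as_tibble(object$correlations, rownames = "property") |>
    tidyr::pivot_longer(-"property", names_to = "pathway", values_to = "r")
  ggplot2::ggplot(df, ggplot2::aes(.data$pathway, .data$property,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "metabolic pathway", y = "property") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Null distributions of the tree-distance permutation test
#'
#' @param object A [leaf_permutation_test()] result.
#' @param ... Unused.
#' @return A ggplot with one panel per distance; the dashed line marks the
#'   observed value.
#' @method autoplot tree_distance_test
#' @export
autoplot.tree_distance_test <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(distance = "branch score", value = object$null_branch_scores,
                   observed = object$branch_score),
    tibble::tibble(distance = "symmetric", value = as.numeric(object$null_symmetric),
                   observed = as.numeric(object$symmetric))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "lightblue", color = "grey40") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$observed),
                        linetype = "dashed", color = "red") +
    ggplot2::facet_wrap(~distance, scales = "free") +
    ggplot2::labs(x = "distance under leaf permutation", y = "count") +
    ggplot2::theme_minimal()
}

#' Learning-curve plot
#'
#' @param curve A [learning_curve()] result.
#' @return A ggplot of mean test AUROC against training-set size, one line
#'   per representation.
#' @export
plot_learning_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$size, .data$mean_auroc,
                                      color = .data$representation)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "training samples", y = "mean test AUROC") +
    ggplot2::theme_minimal()
}
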