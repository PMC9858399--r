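#' Heatmap of one connectivity matrix
#'
#' @param m Symmetric connectivity matrix (with dimnames), or a named
#'   P-vector from [vectorize_fnc()].
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_fnc_matrix <- function(m, title = NULL) {
  if (is.null(dim(m))) m <- unvectorize_fnc(m)
  cn <- colnames(m)
  if (is.null(cn)) cn <- paste0("comp", seq_len(ncol(m)))
  df <- expand.grid(row = cn, col = cn, stringsAsFactors = FALSE)
  df$value <- as.vector(m)
  df$row <- factor(df$row, levels = rev(cn))
  df$col <- factor(df$col, levels = cn)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r", title = title) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot state centroids as connectivity heatmaps
#'
#' @param object A `state_partition`.
#' @param component_names Component labels used to fold centroids back into
#'   matrices; inferred from centroid pair names when possible.
#' @param ... Unused.
#' @return A ggplot object, one facet per state.
#' @method autoplot state_partition
#' @export
autoplot.state_partition <- function(object, component_names = NULL, ...) {
  df <- tidy.state_partition(object)
  df$pair <- factor(df$pair, levels = unique(df$pair))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$value,
                                   fill = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "grey90",
                                  high = "#b2182b") +
    ggplot2::facet_wrap(~state, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "component pair", y = "centroid connectivity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1),
                   legend.position = "none")
}

#' Plot the elbow curve of the cluster-index
#'
#' @param object An `elbow_selection`.
#' @param ... Unused.
#' @return A ggplot of the cluster index over k with the chosen k marked.
#' @method autoplot elbow_selection
#' @export
autoplot.elbow_selection <- function(object, ...) {
  cv <- object$curve
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$k, y = .data$cluster_index)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "number of states k",
                  y = "cluster index (within / between)") +
    ggplot2::theme_minimal()
}

#' State occupancy overview for a cohort
#'
#' @param metrics Output of [compute_state_metrics()].
#' @return A ggplot of per-state fraction-time distributions.
#' @export
plot_state_metrics <- function(metrics) {
  long <- tidyr::pivot_longer(
    metrics, dplyr::starts_with("ft_state"),
    names_to = "state", names_prefix = "ft_state", values_to = "fraction_time")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$state, y = .data$fraction_time)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "state", y = "fraction time") +
    ggplot2::theme_minimal()
}
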