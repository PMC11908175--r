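#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a Jaccard similarity heatmap
#'
#' Tiles the pairwise Jaccard indices of cluster TF codes with clusters
#' arranged most-to-least similar along both axes.
#'
#' @param object a `jaccard_ordering` from [jaccard_ordering()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.jaccard_ordering <- function(object, ...) {
  tidy(object) |>
    dplyr::mutate(cluster_a = factor(.data$cluster_a, object$order),
                  cluster_b = factor(.data$cluster_b, object$order)) |>
    ggplot2::ggplot(ggplot2::aes(.data$cluster_a, .data$cluster_b,
                                 fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a binarised TF code matrix
#'
#' @param object a `binary_code_matrix`; rows ordered by Jaccard
#'   similarity ([jaccard_ordering()]) before tiling.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.binary_code_matrix <- function(object, ...) {
  ord <- jaccard_ordering(object)$order
  tidy(object) |>
    dplyr::mutate(cluster = factor(.data$cluster, ord)) |>
    ggplot2::ggplot(ggplot2::aes(.data$tf, .data$cluster,
                                 fill = factor(.data$bit))) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_manual(values = c("0" = "white", "1" = "black")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "marker",
                  title = object$tf_class) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot neurotransmitter combination counts (UpSet-style bars)
#'
#' @param object an `nt_summary` from [classify_neurotransmitters()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.nt_summary <- function(object, ...) {
  object$combinations |>
    dplyr::mutate(combination = stats::reorder(.data$combination,
                                               -.data$count)) |>
    ggplot2::ggplot(ggplot2::aes(.data$combination, .data$count,
                                 fill = factor(.data$n_positive))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "cells", fill = "classes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-cluster sex-composition bias
#'
#' @param object a `sex_bias_report` from [detect_sex_biased_clusters()].
#' @param ... unused.
#' @return a ggplot of log2 odds ratios, biased clusters highlighted.
#' @export
autoplot.sex_bias_report <- function(object, ...) {
  tibble::as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$cluster, .data$log2_ratio,
                                 fill = .data$biased)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(female = "#c0392b",
                                          male = "#2980b9",
                                          none = "grey75")) +
    ggplot2::labs(x = NULL, y = "log2 observed/expected female odds") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a bulk-correlation coefficient heatmap
#'
#' Cell types in rows, clusters in columns, the assigned (maximal)
#' coefficient of each cluster outlined.
#'
#' @param object a `mapping_result` from [bulk_correlation_map()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mapping_result <- function(object, ...) {
  df <- object$result
  ggplot2::ggplot(df, ggplot2::aes(.data$cluster, .data$cell_type,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(df, .data$assigned),
                       fill = NA, colour = "grey20", linewidth = 0.6) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", high = "#b2182b",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Heatmap of scaled average expression for selected genes
#'
#' The standard marker heatmap: clusters in columns, genes in rows, fill
#' is the cross-cluster z-score of the cluster-mean log expression.
#'
#' @param profile a [cluster_profile()].
#' @param genes gene IDs to show (e.g. from [top_markers()]).
#' @return a ggplot.
#' @export
plot_scaled_heatmap <- function(profile, genes) {
  genes <- intersect(genes, colnames(profile$scaled_avg))
  tidy(profile) |>
    dplyr::filter(.data$gene %in% genes) |>
    dplyr::mutate(gene = factor(.data$gene, genes)) |>
    ggplot2::ggplot(ggplot2::aes(.data$cluster, .data$gene,
                                 fill = .data$scaled_avg)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "scaled\navg") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
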