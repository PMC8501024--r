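#' Association bubble grid
#'
#' The classic integration figure: one bubble per cluster-by-peak-group cell,
#' sized by fold enrichment and coloured by -log10 Fisher p.
#'
#' @param object A `tf_assoc` tibble from [association_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_assoc <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(fe_plot = ifelse(is.finite(.data$fold_enrichment),
                            .data$fold_enrichment, NA_real_),
           neglog_p = -log10(pmax(.data$fisher_p, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$peak_group,
                                   y = .data$cluster_label)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$fe_plot,
                                     colour = .data$neglog_p)) +
    ggplot2::scale_size_area(name = "Fold enrichment", max_size = 14) +
    ggplot2::scale_colour_viridis_c(name = expression(-log[10] * " p")) +
    ggplot2::labs(x = "Peak group (binding dynamics)",
                  y = "Response cluster") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tf_assoc
#' @export
plot_association <- function(object, ...) autoplot.tf_assoc(object, ...)

#' Volcano plot of a DE contrast
#'
#' @param object A `tf_de` tibble (after [call_dysregulated()] for colour).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_de <- function(object, ...) {
  df <- as_tibble(object)
  if (!"direction" %in% names(df)) df$direction <- "none"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$p_value, 1e-300)),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2e6da4",
                                            none = "grey70")) +
    ggplot2::labs(x = expression(log[2] * " fold change"),
                  y = expression(-log[10] * " p")) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tf_de
#' @export
plot_volcano <- function(object, ...) autoplot.tf_de(object, ...)

#' Cluster expression heatmap
#'
#' Relative expression (log2 CPM centred on untreated wild type) of the
#' clustered genes, rows grouped by response program.
#'
#' @param clusters Labelled clusters from [label_clusters()].
#' @param relative_expr Relative-expression tibble covering those genes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_clusters <- function(clusters, relative_expr, ...) {
  df <- relative_expr %>%
    filter(.data$gene_id %in% clusters$gene_id) %>%
    left_join(select(clusters, "gene_id", "label"), by = "gene_id") %>%
    tidyr::pivot_longer(cols = -c("gene_id", "label"),
                        names_to = "sample", values_to = "rel_expr")
  df$sample <- factor(df$sample, levels = unique(df$sample))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$gene_id,
                                   fill = .data$rel_expr)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$label), scales = "free_y",
                        space = "free_y") +
    ggplot2::scale_fill_gradient2(name = "Relative\nexpression",
                                  low = "#2e6da4", mid = "white",
                                  high = "#c0392b") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Binned binding-signal profile heatmap
#'
#' @param mat Matrix from [signal_matrix()] (rows = peaks, columns = bins).
#' @param ... Unused.
#' @return A ggplot object: peaks ordered by total signal, bins on x.
#' @export
plot_signal_matrix <- function(mat, ...) {
  df <- tidyr::expand_grid(peak = seq_len(nrow(mat)), bin = seq_len(ncol(mat)))
  df$signal <- as.vector(t(mat))
  ord <- order(rowSums(mat), decreasing = TRUE)
  df$peak <- match(df$peak, ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$peak,
                                   fill = .data$signal)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Signal") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Bin (window position)", y = "Peak (by total signal)") +
    ggplot2::theme_minimal()
}
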