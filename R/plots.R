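#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_hline geom_vline labs scale_fill_gradient2 theme_minimal
#'   scale_color_manual element_blank theme
#' @export
ggplot2::autoplot

#' Plot sample QC as a PCoA scatter
#' @param object A `sample_qc`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sample_qc <- function(object, ...) {
  p <- ggplot(object$pcoa, aes(x = .data$axis1, y = .data$axis2))
  if ("condition" %in% names(object$pcoa)) {
    p <- p + geom_point(aes(color = .data$condition), size = 3)
  } else {
    p <- p + geom_point(size = 3)
  }
  p + labs(x = "PCoA axis 1", y = "PCoA axis 2",
           title = "Sample PCoA on d = 1 - r") +
    theme_minimal()
}

#' Plot a BIC sweep curve
#' @param object A `bic_sweep`.
#' @param ... Unused.
#' @return A ggplot with the selected K highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.bic_sweep <- function(object, ...) {
  best <- dplyr::filter(object$bic_curve, .data$k == object$best_k)
  ggplot(object$bic_curve, aes(x = .data$k, y = .data$bic)) +
    geom_line() + geom_point() +
    geom_point(data = best, color = "red", size = 3) +
    labs(x = "K", y = "BIC",
         title = sprintf("BIC sweep (best K = %d)", object$best_k)) +
    theme_minimal()
}

#' Plot a row-ordered module heatmap
#' @param object A `heatmap_matrix`.
#' @param ... Unused.
#' @return A ggplot tile map (rows in hierarchical leaf order).
#' @exportS3Method ggplot2::autoplot
autoplot.heatmap_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object$matrix, rownames = "module") |>
    tidyr::pivot_longer(-"module", names_to = "condition", values_to = "z") |>
    dplyr::mutate(module = factor(.data$module, levels = rev(object$row_order)))
  ggplot(df, aes(x = .data$condition, y = .data$module, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    labs(x = NULL, y = NULL, fill = "z") +
    theme_minimal() +
    theme(panel.grid = element_blank())
}

#' MA plot of a DEG table
#' @param deg_table Tibble from [deg_test()].
#' @param p_max Significance flag rule (red points).
#' @return A ggplot.
#' @export
plot_ma <- function(deg_table, p_max = 0.05) {
  df <- ma_data(deg_table, p_max = p_max)
  ggplot(df, aes(x = .data$mean_expr, y = .data$log2fc,
                 color = .data$significant)) +
    geom_point(size = 0.8, alpha = 0.7) +
    scale_color_manual(values = c(`FALSE` = "grey50", `TRUE` = "red")) +
    geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_x_log10() +
    labs(x = "normalized mean expression", y = "log2 fold change") +
    theme_minimal()
}

#' Plot a consensus network (bipartite layout)
#' @param object A `consensus_network`.
#' @param ... Unused.
#' @return A ggplot; TFs as circles, modules as squares, edge color by class.
#' @exportS3Method ggplot2::autoplot
autoplot.consensus_network <- function(object, ...) {
  e <- object$edges
  if (!nrow(e)) {
    return(ggplot() + labs(title = "empty consensus network") + theme_minimal())
  }
  nodes <- dplyr::filter(object$nodes, .data$id %in% c(e$tf, e$module)) |>
    dplyr::group_by(.data$kind) |>
    dplyr::mutate(x = as.numeric(factor(.data$id)),
                  y = ifelse(.data$kind == "tf", 1, 0)) |>
    dplyr::ungroup()
  seg <- e |>
    dplyr::left_join(dplyr::select(nodes, "id", xs = "x", ys = "y"),
                     by = c(tf = "id")) |>
    dplyr::left_join(dplyr::select(nodes, "id", xe = "x", ye = "y"),
                     by = c(module = "id"))
  ggplot() +
    ggplot2::geom_segment(data = seg,
                          aes(x = .data$xs, y = .data$ys,
                              xend = .data$xe, yend = .data$ye,
                              color = .data$class), alpha = 0.7) +
    geom_point(data = nodes,
               aes(x = .data$x, y = .data$y, shape = .data$kind), size = 3) +
    ggplot2::scale_shape_manual(values = c(tf = 16, module = 15)) +
    labs(x = NULL, y = NULL) +
    theme_minimal() +
    theme(axis.text = element_blank(), panel.grid = element_blank())
}
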