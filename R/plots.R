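#' Parallel-coordinates plot of trait log2 ratios with PBCI side panel
#'
#' One line per treatment across the five traits, faceted by condition and
#' colored by classification: blue for promoters/alleviators, red for
#' stress inductors.
#'
#' @param records Output of [pbci_table()] (typically without the control
#'   rows).
#' @return A ggplot object.
#' @export
plot_parallel_coordinates <- function(records) {
  tab <- parallel_coordinates_table(records)
  tab$group <- group_label(tab$treatment, tab$concentration)
  tab$trait <- factor(tab$trait, levels = trait_names)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$trait, y = .data$log2_ratio,
                                    group = .data$group, colour = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::scale_colour_manual(values = c(
      promoter = "#2166ac", alleviator = "#2166ac",
      inductor = "#b2182b", neutral = "grey50"
    )) +
    ggplot2::labs(x = NULL, y = "log2(treatment / control)") +
    ggplot2::theme_minimal()
}

#' Bar chart of PBCI values per treatment and condition
#'
#' @inheritParams plot_parallel_coordinates
#' @return A ggplot object.
#' @export
plot_pbci <- function(records) {
  records$group <- group_label(records$treatment, records$concentration)
  ggplot2::ggplot(records, ggplot2::aes(x = .data$group, y = .data$pbci,
                                        fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::scale_fill_manual(values = c(
      promoter = "#2166ac", alleviator = "#2166ac",
      inductor = "#b2182b", neutral = "grey50"
    )) +
    ggplot2::labs(x = NULL, y = "PBCI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of ln group-mean metabolite concentrations
#'
#' Tile plot of the [heatmap_matrix()] output: metabolite class blocks in
#' rows, treatment x condition groups in columns, significance dots where a
#' treatment differs from its control.
#'
#' @param hm Output of [heatmap_matrix()].
#' @return A ggplot object.
#' @export
plot_heatmap <- function(hm) {
  m <- hm$matrix
  df <- tibble::tibble(
    metabolite = factor(rep(rownames(m), times = ncol(m)), levels = rev(rownames(m))),
    group = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    value = as.vector(m),
    significant = if (is.null(hm$significant)) NA else as.vector(hm$significant)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$metabolite,
                                        fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac",
                                  midpoint = mean(df$value, na.rm = TRUE)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "ln(conc.)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
  if (!all(is.na(df$significant))) {
    p <- p + ggplot2::geom_point(
      data = df[!is.na(df$significant) & df$significant, ], size = 0.8
    )
  }
  p
}

#' PCA biplot
#'
#' Sample (or group) scores overlaid with variable loadings, the loadings
#' rescaled to the score range.
#'
#' @param pca A [pca_svd()] result.
#' @param components Two component indices to display.
#' @return A ggplot object.
#' @export
plot_biplot <- function(pca, components = c(1, 2)) {
  sc <- tibble::as_tibble(pca$scores[, components, drop = FALSE],
                          rownames = "sample")
  names(sc)[2:3] <- c("x", "y")
  ld <- tibble::as_tibble(pca$loadings[, components, drop = FALSE],
                          rownames = "variable")
  names(ld)[2:3] <- c("x", "y")
  scale_f <- 0.8 * min(
    max(abs(sc$x)) / max(abs(ld$x)), max(abs(sc$y)) / max(abs(ld$y))
  )
  ve <- 100 * pca$variance_explained[components]
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_segment(data = ld,
                          ggplot2::aes(x = 0, y = 0, xend = .data$x * scale_f,
                                       yend = .data$y * scale_f),
                          colour = "grey50",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample), size = 2.5,
                       vjust = -0.8) +
    ggplot2::labs(x = sprintf("PC%d (%.1f%%)", components[1], ve[1]),
                  y = sprintf("PC%d (%.1f%%)", components[2], ve[2])) +
    ggplot2::theme_minimal()
}
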