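#' Plot mean standardized trajectories
#'
#' One line per analyte over DOL 0/1/3/7; facet or color by cluster when
#' labels are supplied.
#'
#' @param object A `trajectory_set`.
#' @param labels Optional tibble (`analyte`, `cluster`).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.trajectory_set <- function(object, labels = NULL, ...) {
  df <- as_tibble(object)
  p <- if (is.null(labels)) {
    ggplot(df, aes(x = .data$dol, y = .data$value, group = .data$analyte)) +
      geom_line(alpha = 0.6)
  } else {
    df <- left_join(df, labels, by = "analyte")
    ggplot(df, aes(
      x = .data$dol, y = .data$value, group = .data$analyte,
      colour = factor(.data$cluster)
    )) +
      geom_line(alpha = 0.6) +
      facet_wrap(~cluster) +
      labs(colour = "cluster")
  }
  p +
    scale_x_continuous(breaks = c(0, 1, 3, 7)) +
    labs(
      x = "day of life", y = "mean standardized log10 concentration",
      title = "Analyte trajectories across the first week of life"
    ) +
    theme_minimal()
}

#' Consensus-matrix heatmap
#'
#' Co-clustering frequency matrix ordered by the final cluster labels.
#'
#' @param object An `ontokine_consensus`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ontokine_consensus <- function(object, ...) {
  ord <- object$labels |> arrange(.data$cluster, .data$analyte)
  df <- as_tibble(object$M, rownames = "a1") |>
    tidyr::pivot_longer(-"a1", names_to = "a2", values_to = "consensus")
  df$a1 <- factor(df$a1, levels = ord$analyte)
  df$a2 <- factor(df$a2, levels = ord$analyte)
  ggplot(df, aes(.data$a1, .data$a2, fill = .data$consensus)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "#08306b", limits = c(0, 1)) +
    labs(
      x = NULL, y = NULL,
      title = sprintf(
        "Co-clustering consensus (%s, B = %d)", object$mode, object$B
      )
    ) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, hjust = 1, vjust = 0.5, size = 6),
      axis.text.y = element_text(size = 6))
}

#' PCA score plot
#'
#' Sample scores on the first two principal components, colored by visit
#' when available.
#'
#' @param object An `ontokine_pca`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ontokine_pca <- function(object, ...) {
  df <- object$scores
  expl <- object$explained$var_fraction
  p <- if ("visit" %in% names(df)) {
    ggplot(df, aes(.data$PC1, .data$PC2, colour = factor(.data$visit))) +
      labs(colour = "visit")
  } else {
    ggplot(df, aes(.data$PC1, .data$PC2))
  }
  p +
    geom_point(alpha = 0.5, size = 0.8) +
    labs(
      x = sprintf("PC1 (%.1f%%)", 100 * expl[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * expl[2]),
      title = "PCA of normalized analyte concentrations"
    ) +
    theme_minimal()
}

#' Volcano plot of ontogeny contrasts
#'
#' Median log2 fold change versus -log10 raw p, one panel per follow-up
#' day, with the joint significance/magnitude criterion marked.
#'
#' @param contrasts An `ontokine_contrasts` tibble (run through
#'   [volcano_filter()] or thresholds given here).
#' @param p_cut,lfc_cut Thresholds used to mark hits if `hit` is absent.
#' @return A ggplot.
#' @export
plot_volcano <- function(contrasts, p_cut = 0.01, lfc_cut = 0.2) {
  df <- as_tibble(contrasts)
  if (!"hit" %in% names(df)) {
    df <- volcano_filter(df, p_cut = p_cut, lfc_cut = lfc_cut)
  }
  ggplot(df, aes(.data$median_log2_fc, -log10(pmax(.data$p_raw, 1e-300)),
    colour = .data$hit
  )) +
    geom_point(alpha = 0.7) +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    facet_wrap(~dol, labeller = label_both) +
    labs(
      x = "median log2 fold change vs DOL0", y = "-log10 p (paired test)",
      colour = "flagged"
    ) +
    theme_minimal()
}
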