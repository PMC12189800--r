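# ggplot2 visualisations for each result type.

#' Plot a soft-threshold report
#'
#' Scale-free fit index and mean connectivity against the candidate
#' powers, the standard diagnostic for choosing the soft threshold.
#'
#' @param object A `soft_threshold_report` from [pick_soft_threshold()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.soft_threshold_report <- function(object, ...) {
  df <- as_tibble(object)
  df_long <- tidyr::pivot_longer(df, c("r_squared", "mean_connectivity"),
                                 names_to = "panel", values_to = "value")
  df_long$panel <- factor(df_long$panel, levels = c("r_squared", "mean_connectivity"),
                          labels = c("signed scale-free R²", "mean connectivity"))
  ggplot2::ggplot(df_long, ggplot2::aes(x = .data$beta, y = .data$value)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_text(ggplot2::aes(label = .data$beta), size = 3) +
    ggplot2::geom_vline(xintercept = attr(object, "chosen_beta"),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "soft threshold power", y = NULL)
}

#' Module-stage correlation heatmap
#'
#' One tile per (module, stage) showing the Pearson correlation between
#' the module eigengene and the stage indicator, annotated with the
#' correlation and its p-value.
#'
#' @param object A `module_trait` tibble from [module_trait_correlation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.module_trait <- function(object, ...) {
  df <- as_tibble(object)
  df$stage <- factor(df$stage, levels = attr(object, "stages"))
  df$label <- sprintf("%.2f\n(%.2g)", df$r, df$p_value)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$module,
                                   fill = .data$r)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "white",
                                  high = "red", limits = c(-1, 1)) +
    ggplot2::labs(x = "stage", y = "module", fill = "r")
}

#' Enrichment dot plot
#'
#' Top terms per group by adjusted p, sized by overlap and coloured by
#' significance.
#'
#' @param object An `enrichment_result` from [enrich_groups()].
#' @param top_n Terms shown per group (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, top_n = 10, ...) {
  df <- as_tibble(object)
  df <- dplyr::slice_head(dplyr::group_by(df, .data$group), n = top_n)
  df <- dplyr::ungroup(df)
  df$term <- paste(df$term_id, df$term_name)
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_adj),
                                   y = stats::reorder(.data$term, -.data$p_adj),
                                   size = .data$k, colour = .data$p_adj < 0.05)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL, size = "overlap",
                  colour = "p.adj < 0.05")
}

#' Q trajectory of a Louvain run
#'
#' Modularity after each level of local moving + aggregation; the curve
#' is non-decreasing by construction.
#'
#' @param object A `louvain_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.louvain_result <- function(object, ...) {
  df <- tibble(level = seq_along(object$q_trajectory), q = object$q_trajectory)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$q)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = df$level) +
    ggplot2::labs(x = "level", y = "modularity Q")
}
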