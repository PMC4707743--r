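#' Plot samples on their first two principal components
#'
#' @param object a `linc_pca` object.
#' @param design optional design tibble used to colour points by stage.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.linc_pca <- function(object, design = NULL, ...) {
  df <- object$coords
  if (!is.null(design)) {
    df <- left_join(df, design, by = "library")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(
      if (!is.null(design)) ggplot2::aes(colour = .data$stage), size = 2.5
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_frac[1L]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_frac[2L])
    ) +
    ggplot2::theme_minimal()
  p
}

#' Heatmap of per-module median stage profiles
#'
#' @param profiles tibble from [module_profiles()].
#' @param stage_order optional stage ordering for the x axis.
#' @return a ggplot.
#' @export
plot_module_profiles <- function(profiles, stage_order = NULL) {
  if (!is.null(stage_order)) {
    profiles <- mutate(profiles,
                       stage = factor(.data$stage, levels = stage_order))
  }
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$stage, y = .data$module,
                                         fill = .data$median_expr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "median\nlog2 expr") +
    ggplot2::labs(x = NULL, y = "module") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar chart of per-stage upregulated gene counts
#'
#' @param sets a `linc_stage_sets` object.
#' @param stage_order optional stage ordering.
#' @return a ggplot.
#' @export
plot_stage_upregulation <- function(sets, stage_order = NULL) {
  df <- sets$summary
  if (!is.null(stage_order)) {
    df <- mutate(df, stage = factor(.data$stage, levels = stage_order))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage,
                                   y = .data$n_upregulated)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "upregulated genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
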