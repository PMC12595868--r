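#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot PERMANOVA variance partition
#'
#' Bar chart of the r-squared explained by each factor, residual
#' excluded, with permutation significance annotated.
#'
#' @param object A `permanova_res`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.permanova_res <- function(object, ...) {
  df <- object[object$term != "Residual", ]
  df$label <- ifelse(df$p_value < 0.05, sprintf("p=%.3f", df$p_value), "ns")
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$term, -.data$r_squared),
    y = .data$r_squared)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = expression(R^2),
                  title = "PERMANOVA variance partition") +
    ggplot2::theme_minimal()
}

#' Plot mu_D cell distributions
#'
#' Boxplots of the pairwise Bray-Curtis dissimilarities per within- or
#' between-group cell, the visual companion of [compare_mu_d()].
#'
#' @param object A `mu_d_tbl`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mu_d_tbl <- function(object, ...) {
  df <- tidyr::unnest(
    object[c("cell", "type", "values")],
    cols = "values")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$values,
                                   fill = .data$type)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "Bray-Curtis dissimilarity",
                  title = expression(mu[D] ~ "by cell")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-category environment-wide association contrasts
#'
#' Boxplots of the per-sample aggregated abundance of matched ASVs per
#' category, split by crop.
#'
#' @param object An `ewas_res`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ewas_res <- function(object, ...) {
  ggplot2::ggplot(object$per_sample,
                  ggplot2::aes(x = .data$crop, y = .data$aggregate,
                               fill = .data$crop)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~category, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "aggregated abundance (CPT)",
                  title = "Environment-wide association contrasts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot alpha diversity by group
#'
#' @param alpha Tibble from [alpha_diversity()].
#' @param metadata Metadata with a `crop` column (or another grouping
#'   named via `group`).
#' @param group Metadata column to compare; default `"crop"`.
#' @return A ggplot of boxplots facetted by metric.
#' @export
plot_alpha <- function(alpha, metadata, group = "crop") {
  df <- dplyr::left_join(alpha, metadata, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[group]], y = .data$value,
                                   fill = .data[[group]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Alpha diversity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
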