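#' @importFrom ggplot2 ggplot aes geom_tile geom_text geom_point geom_col
#'   geom_abline scale_fill_gradient2 labs theme_minimal coord_fixed autoplot
NULL

#' Heatmap of pairwise phenotype partial correlations
#'
#' @param x A `pheno_corr` object from
#'   [pairwise_partial_correlations()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pheno_corr <- function(x, ...) {
  df <- dplyr::mutate(tibble::as_tibble(x),
                      label = sprintf("%.3f", .data$r),
                      bold = .data$significant)
  ggplot(df, aes(x = .data$phenotype_a, y = .data$phenotype_b,
                 fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = .data$label,
                  fontface = ifelse(.data$bold, "bold", "plain")),
              size = 3) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    coord_fixed() +
    labs(x = NULL, y = NULL, fill = "partial r",
         title = "Phenotype partial correlations") +
    theme_minimal()
}

#' Heatmap of pairwise signature correlations
#'
#' @param x A `signature_corr` object from
#'   [signature_correlations()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.signature_corr <- function(x, ...) {
  df <- dplyr::mutate(tibble::as_tibble(x),
                      label = sprintf("%.2f", .data$r))
  ggplot(df, aes(x = .data$phenotype_a, y = .data$phenotype_b,
                 fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = .data$label,
                  fontface = ifelse(.data$significant, "bold", "plain")),
              size = 3) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    coord_fixed() +
    labs(x = NULL, y = NULL, fill = "r",
         title = "Neural signature correlations") +
    theme_minimal()
}

#' Predicted-versus-observed plot for a CPM fit
#'
#' @param x A `sleepsig_cpm` object from [cpm_fit_predict()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sleepsig_cpm <- function(x, ...) {
  ggplot(x$predictions, aes(x = .data$observed, y = .data$predicted)) +
    geom_point(alpha = 0.5) +
    geom_abline(linetype = 2) +
    labs(title = sprintf("CPM out-of-fold predictions (r = %.3f)",
                         x$performance_r),
         x = "observed phenotype", y = "predicted") +
    theme_minimal()
}

#' Coefficient map plot for a second-level association map
#'
#' Bars of per-unit coefficients (normalized betas when present),
#' highlighting units surviving the adjusted threshold.
#'
#' @param map Tibble from [map_association()].
#' @param alpha Family alpha; units with `p_adjusted < alpha / 5` are
#'   highlighted (default 0.05).
#' @return A ggplot.
#' @export
plot_association_map <- function(map, alpha = 0.05) {
  val <- if ("beta_normalized" %in% names(map)) "beta_normalized" else "beta"
  df <- dplyr::mutate(map, significant = .data$p_adjusted < alpha / 5,
                      unit = factor(.data$unit, levels = unique(.data$unit)))
  ggplot(df, aes(x = .data$unit, y = .data[[val]],
                 fill = .data$significant)) +
    geom_col() +
    labs(x = "unit", y = val,
         title = paste("Association map:", unique(map$phenotype))) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
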