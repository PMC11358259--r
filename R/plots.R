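#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of a meta-analysis fit
#'
#' Pooled groups (squares, SD x 1.96 interval) and reported-only single
#' studies (open circles) on a common LnBR axis, sorted by estimate, with a
#' dotted zero line. Color encodes the pH class when pooling was stratified
#' by pH.
#'
#' @param object An `lnbr_meta` object from [meta_pool()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lnbr_meta
#' @export
autoplot.lnbr_meta <- function(object, ...) {
  ft <- forest_table(object)
  ft <- ft[ft$flag != "overall", , drop = FALSE]
  ft$label <- factor(ft$label, levels = ft$label[order(ft$estimate)])
  has_ph <- "ph_class" %in% names(ft)
  mapping <- if (has_ph) {
    ggplot2::aes(x = .data$estimate, y = .data$label, color = .data$ph_class)
  } else {
    ggplot2::aes(x = .data$estimate, y = .data$label)
  }
  ggplot2::ggplot(ft, mapping) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.25
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$flag), size = 2.5) +
    ggplot2::scale_shape_manual(
      values = c(pooled = 15, reported_only = 1), name = NULL
    ) +
    ggplot2::labs(
      x = "LnBR (ln ammonium/nitrate biomass ratio)", y = NULL,
      color = "pH class"
    ) +
    ggplot2::theme_minimal()
}

#' Biplot of a trait PCA
#'
#' Species scores on the first two components with trait loading arrows,
#' axes labeled with the percent variance explained.
#'
#' @param object An `lnbr_pca` object from [pca_traits()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lnbr_pca
#' @export
autoplot.lnbr_pca <- function(object, ...) {
  sc <- object$scores
  ld <- object$loadings
  arrow_scale <- 0.8 * min(
    diff(range(sc$PC1)) / diff(range(ld$PC1)),
    diff(range(sc$PC2)) / diff(range(ld$PC2))
  ) / 2
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_segment(
      data = ld,
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * arrow_scale,
                   yend = .data$PC2 * arrow_scale),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      color = "firebrick"
    ) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data$PC1 * arrow_scale, y = .data$PC2 * arrow_scale,
                   label = .data$variable),
      vjust = -0.6, color = "firebrick", size = 3
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$pct_var[1]),
      y = sprintf("PC2 (%.1f%%)", object$pct_var[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot a 15N uptake time course with its linear trend
#'
#' @param totals Tibble of plant-total excess 15N per time (`time_min`,
#'   `excess_g`), e.g. the `plant_totals` output of [run_tracer()].
#' @return A ggplot object with points and the OLS trend (dashed), annotated
#'   with the fitted rate and R^2.
#' @export
plot_uptake <- function(totals) {
  fit <- uptake_trend(totals)
  ggplot2::ggplot(totals, ggplot2::aes(x = .data$time_min, y = .data$excess_g)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(
      intercept = fit$intercept, slope = fit$rate, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "Incubation time (min)", y = "Excess 15N (g)",
      subtitle = sprintf("rate = %.3g g/min, R2 = %.3f", fit$rate, fit$r2)
    ) +
    ggplot2::theme_minimal()
}
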