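#' Plot a rank-enrichment curve
#'
#' Cumulative recovery of the gene set against rank fraction, with the
#' diagonal expected under no enrichment; the signed area between the two
#' is the enrichment statistic.
#'
#' @param object a `rank_enrichment`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rank_enrichment <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$rank_frac, y = .data$cum_frac)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_step(colour = "firebrick") +
    ggplot2::labs(
      x = "Rank fraction", y = "Cumulative set fraction",
      subtitle = sprintf("area = %.3f, p = %.2g",
                         object$area_stat, object$p)) +
    ggplot2::theme_minimal()
}

#' Plot sample PC scores
#'
#' @param object a `pc_scores`.
#' @param colour_by optional vector (one value per sample) mapped to colour.
#' @param axes the two components to plot.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pc_scores <- function(object, colour_by = NULL, axes = c(1, 2),
                               ...) {
  df <- tibble::tibble(
    x = object$scores[, axes[1]], y = object$scores[, axes[2]],
    colour = colour_by %||% "sample")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$colour)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = colnames(object$scores)[axes[1]],
                  y = colnames(object$scores)[axes[2]],
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Myeloid vs lymphoid composite-score scatter plot
#'
#' @param composites tibble from [assign_subgroups()].
#' @param t the subgroup threshold drawn as guide lines.
#' @return a ggplot.
#' @export
plot_subgroups <- function(composites, t = 0.05) {
  ggplot2::ggplot(composites,
                  ggplot2::aes(x = .data$myeloid, y = .data$lymphoid,
                               colour = .data$subgroup)) +
    ggplot2::geom_hline(yintercept = c(-t, t), linetype = 3) +
    ggplot2::geom_vline(xintercept = c(-t, t), linetype = 3) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Myeloid composite score",
                  y = "Lymphoid composite score", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Null-distribution plot for the GWAS distance resampling test
#'
#' @param object a `proximity_null`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.proximity_null <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(null = object$null),
                  ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(x = "Null mean nearest-locus distance (bp)",
                  y = "Trials",
                  subtitle = sprintf("observed = %.0f bp, empirical p = %.3g",
                                     object$observed, object$p)) +
    ggplot2::theme_minimal()
}
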