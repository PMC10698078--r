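#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_col
#'   geom_errorbar geom_text geom_vline labs theme_minimal position_stack
#' @export
ggplot2::autoplot

#' Scatter plot of a linear fit
#'
#' Observations with the fitted OLS line; the standard companion figure for
#' the enrichment regressions.
#'
#' @param object A `linear_fit`.
#' @param xlab,ylab Axis labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot linear_fit
#' @export
autoplot.linear_fit <- function(object, xlab = "x", ylab = "y", ...) {
  df <- tibble::tibble(x = object$x, y = object$y)
  ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_point(alpha = 0.8) +
    geom_abline(slope = object$slope, intercept = object$intercept,
                linewidth = 0.6) +
    labs(
      x = xlab, y = ylab,
      subtitle = sprintf("y = %.3g x + %.3g, R = %.3f, P = %.3g",
                         object$slope, object$intercept, object$r, object$p_slope)
    ) +
    theme_minimal()
}

#' Threshold figure: enrichment against C/N with the x-intercept marked
#'
#' @param object A `threshold_estimate`.
#' @param xlab,ylab Axis labels.
#' @param ... Unused.
#' @return A ggplot object with the fitted line, the threshold marker and a
#'   shaded bootstrap interval.
#' @method autoplot threshold_estimate
#' @export
autoplot.threshold_estimate <- function(object, xlab = "C/N ratio",
                                        ylab = "enrichment", ...) {
  fit <- object$fit
  autoplot(fit, xlab = xlab, ylab = ylab) +
    ggplot2::annotate("rect", xmin = object$ci_low, xmax = object$ci_high,
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    geom_vline(xintercept = object$x_intercept, linetype = 2) +
    labs(subtitle = sprintf(
      "threshold %.2f (95%% CI %.2f-%.2f)",
      object$x_intercept, object$ci_low, object$ci_high
    ))
}

#' Group means with Tukey letters
#'
#' Bar chart of group means +/- SE annotated with the compact letter
#' display; groups sharing a letter do not differ at the configured alpha.
#'
#' @param object An `anova_tukey` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot anova_tukey
#' @export
autoplot.anova_tukey <- function(object, ...) {
  gs <- object$group_stats
  ggplot(gs, aes(x = stats::reorder(.data$group, -.data$mean), y = .data$mean)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
                  width = 0.2) +
    geom_text(aes(y = .data$mean + .data$se, label = .data$letters),
              vjust = -0.6) +
    labs(x = NULL, y = if (object$log_transformed) "mean (log scale)" else "mean") +
    theme_minimal()
}

#' Stacked community composition bars
#'
#' Relative abundance of fungal species per plant, the standard way to show
#' an ectomycorrhizal assemblage across sampling dates.
#'
#' @param morphotypes,census Input tables as in [relative_abundance()].
#' @return A ggplot object faceted by sampling date.
#' @export
plot_community_composition <- function(morphotypes, census) {
  long <- relative_abundance(morphotypes, census)
  ggplot(long, aes(x = .data$plant_id, y = .data$rel_abundance,
                   fill = .data$species)) +
    geom_col(position = position_stack()) +
    ggplot2::facet_wrap(~time_point, scales = "free_x") +
    labs(x = NULL, y = "relative abundance") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
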