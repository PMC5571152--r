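#' Forest-style figure for a meta-analysis summary
#'
#' Mean percent change per category with its 95% bootstrap interval, drawn
#' as point-and-range; significant categories (interval excluding zero) are
#' filled. Facetted by moderator level when the summary is stratified.
#'
#' @param object A `meta_summary` tibble from [run_meta_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meta_summary
#' @export
autoplot.meta_summary <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !.data$insufficient_data)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$percent_change, y = .data$group_label,
    xmin = .data$percent_ci_low, xmax = .data$percent_ci_high,
    shape = .data$significant
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange() +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(
      x = sprintf("Change relative to %s (%%), with 95%% CI",
                  control_option()),
      y = NULL,
      title = unique(df$response)
    ) +
    ggplot2::theme_minimal()
  if (any(df$moderator_level != "<none>")) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$moderator_level))
  }
  p
}

#' @rdname autoplot.meta_summary
#' @export
plot_meta_forest <- function(object, ...) autoplot.meta_summary(object, ...)

#' Least-squares means figure for a mixed-model fit
#'
#' Option LS means with +/- 1 SE bars and the compact letters at `alpha`.
#'
#' @param object A `"reml_fit"` object.
#' @param alpha Significance level for the letters.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot reml_fit
#' @export
autoplot.reml_fit <- function(object, alpha = 0.05, ...) {
  df <- tidy(object, alpha = alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$option, y = .data$ls_mean)) +
    ggplot2::geom_col(fill = "grey80", colour = "grey30") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ls_mean - .data$se,
                                        ymax = .data$ls_mean + .data$se),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters,
                                    y = .data$ls_mean + 1.5 * .data$se),
                       vjust = 0) +
    ggplot2::labs(x = NULL,
                  y = sprintf("LS mean (%s)", object$response),
                  title = "Mixed-model least-squares means") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
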