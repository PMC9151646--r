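#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a stabilogram with its 95% confidence ellipse
#'
#' The sway path in the support plane (ML on x, AP on y) with the fitted
#' 95% confidence ellipse overlaid.
#'
#' @param object A `stabilogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stabilogram <- function(object, ...) {
  ell <- confidence_ellipse(object)
  th <- seq(0, 2 * pi, length.out = 181)
  a <- ell$ELLIPSE_MAIN_AXIS / 2; b <- ell$ELLIPSE_MINOR_AXIS / 2
  phi <- ell$ELLIPSE_ORIENTATION
  ellipse_df <- tibble::tibble(
    ml = a * cos(th) * cos(phi) - b * sin(th) * sin(phi),
    ap = a * cos(th) * sin(phi) + b * sin(th) * cos(phi)
  )
  df <- tibble::tibble(ml = object$ml, ap = object$ap)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ml, y = .data$ap)) +
    ggplot2::geom_path(alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_path(data = ellipse_df, colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "ML displacement (cm)", y = "AP displacement (cm)",
                  title = "Stabilogram with 95% confidence ellipse") +
    ggplot2::theme_minimal()
}

#' Plot electrode-wise test results
#'
#' POST-minus-PRE mean differences per electrode with FDR-significant
#' electrodes highlighted, faceted by band (and group when present).
#'
#' @param object An `electrode_stats` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.electrode_stats <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$channel <- factor(df$channel, levels = unique(df$channel))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$mean_diff,
                                        fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "Relative-power difference (POST - PRE)",
                  fill = "FDR significant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 5))
  facets <- intersect(c("group", "band"), names(df))
  if (length(facets) > 0)
    p <- p + ggplot2::facet_wrap(facets, ncol = 1)
  p
}

#' Plot classifier metrics
#'
#' Accuracy, sensitivity, and specificity per model, grouped by feature
#' selection when present.
#'
#' @param object A `classifier_metrics` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.classifier_metrics <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$value,
                                        fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Percent", fill = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
  if ("selection" %in% names(df))
    p <- p + ggplot2::facet_wrap("selection")
  p
}

#' Plot heart-rate phase summaries
#'
#' Phase means with one-SD error bars in protocol order.
#'
#' @param hr_features Output of [hr_summary()].
#' @return A ggplot.
#' @export
plot_hr_phases <- function(hr_features) {
  df <- hr_features
  df$phase <- factor(df$phase, levels = c("baseline", "pre", "p25", "p50",
                                          "p75", "post"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$mean_bpm)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_bpm - .data$sd_bpm,
                                          ymax = .data$mean_bpm + .data$sd_bpm)) +
    ggplot2::labs(x = "Protocol phase", y = "Heart rate (bpm)") +
    ggplot2::theme_minimal()
}
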