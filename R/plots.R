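# ggplot2 views of the pipeline's result types.

#' Plot genotype stress trajectories
#'
#' Daily genotype means of the average percentage stress with standard-error
#' bars, one line per genotype.
#'
#' @param object A `stress_phenotypes` tibble (see [compute_phenotypes()]).
#' @param moving_average If `TRUE`, plot the per-plant moving average
#'   (genotype-averaged) instead of the raw percentage stress.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stress_phenotypes
#' @export
autoplot.stress_phenotypes <- function(object, moving_average = FALSE, ...) {
  df <- drop_flagged(object)
  if (moving_average) df$percentage_stress <- df$moving_average
  summ <- genotype_average(df)
  ylab <- if (moving_average) "Moving average percentage stress" else
    "Average percentage stress"
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$dag, y = .data$mean,
                                     colour = .data$genotype)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$stderr,
                                        ymax = .data$mean + .data$stderr),
                           width = 0.4, alpha = 0.7) +
    ggplot2::labs(x = "Days after germination", y = ylab, colour = "Genotype") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.stress_phenotypes
#' @export
plot_genotype_series <- function(object, moving_average = FALSE) {
  autoplot.stress_phenotypes(object, moving_average = moving_average)
}

#' Plot the classifier comparison
#'
#' Validation and test accuracy per family, in the canonical family order.
#'
#' @param object A `stress_classifier_bundle`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stress_classifier_bundle
#' @export
autoplot.stress_classifier_bundle <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), c("validation_accuracy", "test_accuracy"),
                            names_to = "set", values_to = "accuracy")
  df$set <- sub("_accuracy", "", df$set)
  df$family <- factor(df$family, levels = rev(family_order))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accuracy, y = .data$family,
                                   fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(xlim = c(min(df$accuracy) * 0.98, 1)) +
    ggplot2::labs(x = "Held-out accuracy", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
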