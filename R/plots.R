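#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Correlation and Bland-Altman plots for an agreement report
#'
#' `type = "correlation"` plots predicted against gold with the identity and
#' calibration lines; `type = "bland_altman"` plots the differences against
#' the pair means with the bias and 1.96-SD limits of agreement.
#'
#' @param object A `tm_agreement` from [evaluate_agreement()].
#' @param type `"correlation"` or `"bland_altman"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tm_agreement <- function(object,
                                  type = c("correlation", "bland_altman"),
                                  ...) {
  type <- match.arg(type)
  df <- tidy(object)
  if (type == "correlation") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$gold)) +
      ggplot2::geom_abline(slope = 1, intercept = 0,
                           linetype = "dashed", colour = "grey50") +
      ggplot2::geom_abline(slope = object$slope,
                           intercept = object$intercept, colour = "steelblue") +
      ggplot2::geom_point() +
      ggplot2::labs(
        x = "Predicted (thermal features)", y = "Gold standard (EMG)",
        title = sprintf("r = %.3f (p = %.2g), RMSE_z = %.3f",
                        object$r, object$r_p, object$rmse_z)
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_pair, y = .data$difference)) +
      ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
      ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                          linetype = "dashed", colour = "grey40") +
      ggplot2::geom_point() +
      ggplot2::labs(
        x = "Mean of predicted and gold", y = "Predicted - gold",
        title = sprintf("bias = %.3g, LoA [%.3g, %.3g]",
                        object$bias, object$loa_low, object$loa_high)
      ) +
      ggplot2::theme_minimal()
  }
}

#' Out-of-fold prediction plot for a cross-validation result
#'
#' @param object A `tm_cv` from [nested_loso_cv()].
#' @param ... Unused.
#' @return A ggplot of gold against predicted, coloured by subject.
#' @export
autoplot.tm_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$gold,
                                   colour = .data$subject_id)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("Predicted %s", toupper(object$target)),
      y = sprintf("EMG %s", toupper(object$target)),
      colour = "Subject",
      title = sprintf("%s, ROI %s: r = %.3f, RMSE_z = %.3f",
                      object$family, paste(object$roi, collapse = "/"),
                      object$r, object$rmse_z)
    ) +
    ggplot2::theme_minimal()
}

#' F-score bar chart across features, ROIs and targets
#'
#' @param scores A tibble from [score_grid()].
#' @return A ggplot object, faceted by target.
#' @export
plot_feature_scores <- function(scores) {
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$feature, y = .data$f_statistic,
                               fill = factor(.data$roi_id))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ .data$target, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "F statistic", fill = "ROI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
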