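# ggplot2 visualisations for the result types.

#' @exportS3Method ggplot2::autoplot
autoplot.roc_points <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "ROC curve") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = factor(.data$n_hidden), y = .data$test_auc,
                               colour = .data$input_set)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.1),
                        alpha = 0.7) +
    ggplot2::labs(x = "Hidden neurons", y = "Test-fold AUC",
                  colour = "Input set",
                  title = "Nested cross-validation grid") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.hydropathy_comparison <- function(object, ...) {
  lab <- ifelse(object$p < 0.05, sprintf("p=%.2g", object$p), "")
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$position),
                                       y = .data$mean_diff)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_text(ggplot2::aes(label = lab),
                       vjust = ifelse(object$mean_diff < 0, 1.4, -0.6),
                       size = 3) +
    ggplot2::labs(x = "Peptide position",
                  y = "Mean hydropathy difference (A - B)",
                  title = "Positional hydropathy comparison",
                  subtitle = "Below zero: pool A more hydrophobic") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.sasa_result <- function(object, ...) {
  pr <- tidyr::pivot_longer(object$per_residue, c("total", "hydrophobic"),
                            names_to = "kind", values_to = "area")
  ggplot2::ggplot(pr, ggplot2::aes(x = factor(.data$position),
                                   y = .data$area, fill = .data$kind)) +
    ggplot2::geom_col(position = "identity", alpha = 0.7) +
    ggplot2::labs(x = "Peptide position", y = expression("SASA ("*ring(A)^2*")"),
                  fill = NULL, title = "Peptide solvent accessibility") +
    ggplot2::theme_minimal()
}
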