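#' Plot cross-validated AUC per category
#'
#' @param object An `mlr_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mlr_cv <- function(object, ...) {
  per <- object$per_repeat
  ggplot2::ggplot(per, ggplot2::aes(x = .data$category, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      title = sprintf("Repeated %d-fold CV AUC (%s colour)",
                      object$folds, object$trait),
      x = NULL, y = "one-vs-rest AUC"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the forward-selection AIC trace
#'
#' @param object An `mlr_selection` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mlr_selection <- function(object, ...) {
  tr <- object$trace
  tr$label <- ifelse(is.na(tr$added), "(empty)", tr$added)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$aic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(
      title = sprintf("Forward AIC selection (%s colour)", object$trait),
      x = "markers added", y = "AIC"
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of per-category concordance metrics
#'
#' @param metrics Tibble from [concordance_metrics()].
#' @param title Optional plot title.
#' @return A ggplot.
#' @export
plot_metrics <- function(metrics, title = "Prediction performance") {
  long <- metrics |>
    dplyr::select("category", "accuracy", "sensitivity", "specificity",
                  "ppv", "npv") |>
    tidyr::pivot_longer(-"category", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(x) 100 * x) +
    ggplot2::labs(title = title, x = NULL, y = "%", fill = NULL) +
    ggplot2::theme_minimal()
}
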