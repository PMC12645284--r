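# ggplot2 autoplot methods for the main result types

#' @describeIn nested_cv fold-metric overview plot.
#' @param object a `cv_result`.
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- object$folds %>%
    select("fold", "accuracy", "precision", "recall", "f1", "roc_auc", "brier") %>%
    tidyr::pivot_longer(-"fold", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 1.8, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "outer-fold value",
                  title = paste(object$algorithm, "+", object$features)) +
    ggplot2::theme_minimal()
}

#' @describeIn calibration_curves similarity-resolved calibration plot.
#' @param object a `calibration_set`.
#' @param ... unused.
#' @export
autoplot.calibration_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_prob, y = .data$obs_freq,
                                       colour = .data$similarity_group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "mean predicted probability", y = "observed positive frequency",
                  colour = "similarity", size = "bin size") +
    ggplot2::theme_minimal()
}

#' @describeIn feature_report top-k global importance bar chart.
#' @param object a `feature_report`.
#' @export
autoplot.feature_report <- function(object, ...) {
  k <- attr(object, "k")
  top <- head(tidy(object), k)
  ggplot2::ggplot(top, ggplot2::aes(x = stats::reorder(.data$feature, .data$share),
                                    y = .data$share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "share of total mean |Shapley value|") +
    ggplot2::theme_minimal()
}

#' @describeIn gate applicability-domain verdict counts.
#' @param object an `ad_report`.
#' @export
autoplot.ad_report <- function(object, ...) {
  counts <- object %>% dplyr::count(.data$verdict)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$verdict, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "samples") +
    ggplot2::theme_minimal()
}
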