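# broom-style tidy()/glance() methods for the fitted result objects

#' @describeIn nested_cv per-fold metrics as a tibble.
#' @param x a `cv_result`.
#' @param ... unused.
#' @export
tidy.cv_result <- function(x, ...) {
  x$folds %>%
    mutate(n_bits = vapply(.data$chosen, function(c) {
             if (is.null(c$fp)) NA_integer_ else as.integer(c$fp$n_bits)
           }, integer(1)),
           max_path = vapply(.data$chosen, function(c) {
             if (is.null(c$fp)) NA_integer_ else as.integer(c$fp$max_path)
           }, integer(1))) %>%
    select(-"chosen")
}

#' @describeIn nested_cv one-row mean/SD summary across outer folds.
#' @export
glance.cv_result <- function(x, ...) {
  f <- x$folds
  tibble(
    algorithm = x$algorithm, features = x$features, n_folds = nrow(f),
    accuracy = mean(f$accuracy), accuracy_sd = sd(f$accuracy),
    precision = mean(f$precision, na.rm = TRUE),
    precision_sd = sd(f$precision, na.rm = TRUE),
    recall = mean(f$recall, na.rm = TRUE), recall_sd = sd(f$recall, na.rm = TRUE),
    f1 = mean(f$f1), f1_sd = sd(f$f1),
    roc_auc = mean(f$roc_auc, na.rm = TRUE), roc_auc_sd = sd(f$roc_auc, na.rm = TRUE),
    brier = mean(f$brier), brier_sd = sd(f$brier),
    seed = x$seed
  )
}

#' @describeIn compare_configs pairwise Conover comparisons as a tibble.
#' @param x a `comparison_report`.
#' @param ... unused.
#' @export
tidy.comparison_report <- function(x, ...) x$pairwise

#' @describeIn compare_configs one-row Friedman summary.
#' @export
glance.comparison_report <- function(x, ...) {
  tibble(metric = x$metric, friedman_statistic = x$friedman_statistic,
         friedman_p = x$friedman_p, n_configurations = length(x$configurations),
         n_folds = x$n_folds)
}

#' @describeIn shap_values non-zero attributions in long form.
#' @param x a `shap_attribution`.
#' @param ... unused.
#' @export
tidy.shap_attribution <- function(x, ...) {
  idx <- which(x$values != 0, arr.ind = TRUE)
  tibble(sample = idx[, 1], feature = x$feature_names[idx[, 2]],
         shap = x$values[idx]) %>%
    arrange(.data$sample, desc(abs(.data$shap)))
}

#' @describeIn shap_values base value, local-accuracy error and dimensions.
#' @export
glance.shap_attribution <- function(x, ...) {
  tibble(n_samples = nrow(x$values), n_features = ncol(x$values),
         base_value = x$base_value,
         max_local_accuracy_error =
           max(abs(rowSums(x$values) + x$base_value - x$prob)))
}

#' @describeIn feature_report ranked features as a plain tibble.
#' @param x a `feature_report`.
#' @param ... unused.
#' @export
tidy.feature_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "feature_report")
  out
}

#' @describeIn feature_report top-feature and top-k cumulative shares.
#' @export
glance.feature_report <- function(x, ...) {
  tibble(n_features = nrow(x), top_share = attr(x, "top_share"),
         k = attr(x, "k"), top_k_share = attr(x, "top_k_share"))
}
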