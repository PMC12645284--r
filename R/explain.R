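# Shapley-value explanation of fitted forests: global feature ranking,
# decomposition of fingerprint-bit attributions onto trimer atoms, bit
# collision reporting, and pairwise interaction scanning.

#' Select a configuration by plain stratified k-fold cross-validation
#'
#' The same grid-search procedure as the inner loop of [nested_cv()], run
#' once on the full dataset; used to pick the configuration behind the
#' full-data refit that the explanation and applicability-domain analyses
#' use.
#'
#' @inheritParams nested_cv
#' @param k number of folds (default 5).
#' @return list with `fp` (fingerprint config or NULL) and `model`
#'   (model hyperparameters), plus `cv_accuracy`.
#' @export
select_config <- function(data, algorithm = c("rf", "nn"),
                          features = c("fingerprint", "descriptor"),
                          grid = hyper_grid(), k = 5, seed = 1,
                          extra_features = NULL) {
  algorithm <- match.arg(algorithm)
  features <- match.arg(features)
  data <- as_tibble(data)
  smiles <- smiles_column(data)
  y <- as.integer(data$label)
  configs <- enumerate_configs(grid, algorithm, features)
  sets <- prepare_feature_sets(smiles, features, grid, extra_features)
  set.seed(seed)
  fold <- make_stratified_folds(y, k)
  fit_seeds <- sample.int(.Machine$integer.max, length(configs) * k)
  acc <- numeric(length(configs))
  fi <- 0L
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    xy_by_key <- list()
    for (ci in seq_along(configs)) {
      cfg <- configs[[ci]]
      key <- config_matrix_key(cfg)
      if (is.null(xy_by_key[[key]])) {
        m <- sets[[key]]
        keep <- matrixStats_colVars(m[tr, , drop = FALSE]) > 0
        xy_by_key[[key]] <- list(tr = m[tr, keep, drop = FALSE],
                                 te = m[te, keep, drop = FALSE])
      }
      xy <- xy_by_key[[key]]
      fi <- fi + 1L
      fit <- fit_model(algorithm, xy$tr, y[tr], cfg$model, fit_seeds[fi])
      p <- predict_prob(fit, xy$te)
      acc[ci] <- acc[ci] + mean((p > 0.5) == (y[te] == 1)) / k
    }
  }
  best <- configs[[which.max(acc)]]
  best$cv_accuracy <- max(acc)
  best
}

#' Fit the final full-data model
#'
#' Selects a configuration with [select_config()], refits it on all samples
#' (zero-variance features removed on the full dataset), and keeps the
#' fingerprint traces needed for atom-level attribution.
#'
#' @inheritParams select_config
#' @return a `final_model` object with elements `model`, `config`,
#'   `feature_matrix` (filtered), `fp` (full `feature_matrix` object for
#'   fingerprints, with bit traces), `data`.
#' @export
final_model <- function(data, algorithm = c("rf", "nn"),
                        features = c("fingerprint", "descriptor"),
                        grid = hyper_grid(), seed = 1) {
  algorithm <- match.arg(algorithm)
  features <- match.arg(features)
  data <- as_tibble(data)
  y <- as.integer(data$label)
  cfg <- select_config(data, algorithm, features, grid, seed = seed)
  fp <- NULL
  if (features == "fingerprint") {
    fp <- fingerprint(data, fp_config(cfg$fp$n_bits, cfg$fp$max_path))
    full <- fp$matrix
  } else {
    full <- descriptors(data)$matrix
  }
  keep <- matrixStats_colVars(full) > 0
  X <- full[, keep, drop = FALSE]
  set.seed(seed)
  fit <- fit_model(algorithm, X, y, cfg$model, sample.int(.Machine$integer.max, 1))
  structure(
    list(model = fit, config = cfg, feature_matrix = X, variance_mask = keep,
         fp = fp, data = data, algorithm = algorithm, features = features,
         seed = seed),
    class = "final_model"
  )
}

#' @export
print.final_model <- function(x, ...) {
  cat("<final_model> ", x$algorithm, " + ", x$features, ", ",
      nrow(x$feature_matrix), " samples x ", ncol(x$feature_matrix),
      " retained features\n", sep = "")
  invisible(x)
}

#' Exact Shapley values for a fitted tree ensemble
#'
#' Tree-path-dependent Shapley values on the probability scale, computed
#' exactly by per-leaf coalition enumeration (feasible because the forests
#' here are shallow). Local accuracy holds per sample: the attributions plus
#' the base value equal the predicted probability.
#'
#' @param model a `polybiodeg_rf` (or `final_model` wrapping one).
#' @param X feature matrix to explain (default: the training matrix).
#' @return a `shap_attribution`: list with `values` (samples x features),
#'   `base_value`, `feature_names`, and the explained `prob`.
#' @export
shap_values <- function(model, X = NULL) {
  fm <- NULL
  if (inherits(model, "final_model")) { fm <- model; model <- model$model }
  if (!inherits(model, "polybiodeg_rf")) {
    abort("Shapley explanation requires a tree-ensemble model",
          class = "polybiodeg_contract_error")
  }
  if (is.null(X)) X <- model$X_train
  if (ncol(X) != length(model$feature_names)) {
    abort("feature-space mismatch between model and data",
          class = "polybiodeg_contract_error")
  }
  forest <- rf_forest_arrays(model)
  storage.mode(X) <- "double"
  res <- forest_shap_cpp(forest, X, ncol(X))
  values <- res$phi
  colnames(values) <- model$feature_names
  structure(
    list(values = values, base_value = res$base,
         feature_names = model$feature_names,
         prob = predict_prob(model, X), X = X, final_model = fm),
    class = "shap_attribution"
  )
}

#' @export
print.shap_attribution <- function(x, ...) {
  cat("<shap_attribution> ", nrow(x$values), " samples x ", ncol(x$values),
      " features, base value ", round(x$base_value, 4), "\n", sep = "")
  invisible(x)
}

#' Decompose fingerprint-bit Shapley values onto trimer atoms
#'
#' Each bit present in the molecule splits its Shapley value equally over
#' the union of atoms of the fragment(s) that set it in that molecule;
#' absent-bit attributions have no atoms and are reported separately.
#'
#' @param attr a `shap_attribution` over fingerprint bits.
#' @param bit_trace per-sample trace list from [fingerprint()] (taken from
#'   the wrapped `final_model` if available).
#' @param sample sample index to decompose.
#' @return list with `atom_scores` (tibble `atom`, `score`),
#'   `absent_total` (summed Shapley value of absent bits) and
#'   `present_total`.
#' @export
atoms_from_bits <- function(attr, bit_trace = NULL, sample = 1) {
  if (is.null(bit_trace)) {
    if (is.null(attr$final_model) || is.null(attr$final_model$fp)) {
      abort("bit_trace required", class = "polybiodeg_contract_error")
    }
    bit_trace <- attr$final_model$fp$bit_trace
  }
  tr <- bit_trace[[sample]]
  phi <- attr$values[sample, ]
  bit_ids <- as.integer(sub("^b", "", attr$feature_names))
  present <- tibble(feature = attr$feature_names, bit = bit_ids, phi = unname(phi)) %>%
    mutate(has_fragment = .data$bit %in% tr$bit)
  # a bit can be "present" only via its trace here; the model matrix agrees by
  # construction, and a set bit without trace is an integrity error
  x_row <- if (!is.null(attr$X)) attr$X[sample, ] else NULL
  if (!is.null(x_row)) {
    set_no_trace <- which(x_row == 1 & !present$has_fragment)
    if (length(set_no_trace) > 0) {
      abort("bit set in feature matrix but missing from trace",
            class = "polybiodeg_integrity_error")
    }
  }
  atoms_by_bit <- split(tr$atoms, tr$bit)
  acc <- numeric(0)  # accumulated per atom id (as character)
  for (k in which(present$has_fragment & present$phi != 0)) {
    at <- unique(unlist(atoms_by_bit[[as.character(present$bit[k])]],
                        use.names = FALSE))
    per <- present$phi[k] / length(at)
    key <- as.character(at)
    hit <- match(key, names(acc))
    new <- is.na(hit)
    if (any(new)) {
      acc <- c(acc, setNames(rep(0, sum(new)), key[new]))
      hit <- match(key, names(acc))
    }
    acc[hit] <- acc[hit] + per
  }
  atom_scores <- tibble(atom = as.integer(names(acc)), score = unname(acc)) %>%
    arrange(.data$atom)
  list(atom_scores = atom_scores,
       present_total = sum(present$phi[present$has_fragment]),
       absent_total = sum(present$phi[!present$has_fragment]))
}

#' Global feature report: ranking, shares and bit collisions
#'
#' Features are ranked by mean absolute Shapley value over samples (ties by
#' feature index); each feature's share is its mean absolute value divided by
#' the total. For fingerprints, every bit's distinct fragment path strings
#' across the dataset are collected, so bits set by several chemically
#' distinct moieties (collisions) are visible.
#'
#' @param attr a `shap_attribution`.
#' @param bit_trace optional per-sample trace list (defaults to the wrapped
#'   model's).
#' @param k top-k cutoff for the cumulative share (default 20).
#' @return a `feature_report`: tibble of ranked features with `share`,
#'   `cumulative_share`, `n_fragments`, plus attributes `top_share`,
#'   `top_k_share`.
#' @export
feature_report <- function(attr, bit_trace = NULL, k = 20) {
  stopifnot(nrow(attr$values) >= 1)
  if (is.null(bit_trace) && !is.null(attr$final_model) && !is.null(attr$final_model$fp)) {
    bit_trace <- attr$final_model$fp$bit_trace
  }
  mean_abs <- colMeans(abs(attr$values))
  total <- sum(mean_abs)
  rep <- tibble(feature = attr$feature_names, mean_abs_shap = unname(mean_abs)) %>%
    arrange(desc(.data$mean_abs_shap), .data$feature) %>%
    mutate(rank = row_number(),
           share = if (total > 0) .data$mean_abs_shap / total else 0,
           cumulative_share = cumsum(.data$share))
  if (!is.null(bit_trace)) {
    frag <- bind_rows(bit_trace) %>%
      mutate(feature = paste0("b", .data$bit)) %>%
      group_by(.data$feature) %>%
      summarise(n_fragments = dplyr::n_distinct(.data$path),
                fragments = list(sort(unique(.data$path))), .groups = "drop")
    rep <- left_join(rep, frag, by = "feature")
  }
  structure(rep,
            class = c("feature_report", class(rep)),
            top_share = rep$share[1],
            top_k_share = sum(rep$share[seq_len(min(k, nrow(rep)))]),
            k = k)
}

#' Pairwise Shapley interaction scan
#'
#' Exact Shapley interaction values (per-leaf coalition enumeration); the
#' symmetric off-diagonal cells each carry half the pairwise interaction, and
#' the full matrix sums to the prediction minus the base value.
#'
#' @param model a `polybiodeg_rf` or `final_model`.
#' @param X samples to scan (default: training matrix).
#' @param samples indices of samples to include (default: all rows of `X`).
#' @return an `interaction_scan` object: list with `pairs` (tibble of mean
#'   and mean-absolute interaction per feature pair), `max_off_diagonal`,
#'   `max_main_effect` and `relative_strength`.
#' @export
interaction_scan <- function(model, X = NULL, samples = NULL) {
  if (inherits(model, "final_model")) model <- model$model
  if (!inherits(model, "polybiodeg_rf")) {
    abort("interaction scan requires a tree-ensemble model",
          class = "polybiodeg_contract_error")
  }
  if (is.null(X)) X <- model$X_train
  if (is.null(samples)) samples <- seq_len(nrow(X))
  forest <- rf_forest_arrays(model)
  storage.mode(X) <- "double"
  p <- ncol(X)
  sum_abs <- matrix(0, p, p)
  sum_val <- matrix(0, p, p)
  for (i in samples) {
    I <- forest_shap_interactions_cpp(forest, X[i, ], p)
    sum_abs <- sum_abs + abs(I)
    sum_val <- sum_val + I
  }
  n <- length(samples)
  mean_abs <- sum_abs / n
  off <- mean_abs; diag(off) <- 0
  ut <- which(upper.tri(mean_abs), arr.ind = TRUE)
  pairs <- tibble(
    feature1 = colnames(X)[ut[, 1]], feature2 = colnames(X)[ut[, 2]],
    mean_abs_interaction = mean_abs[ut],
    mean_interaction = (sum_val / n)[ut]
  ) %>% arrange(desc(.data$mean_abs_interaction))
  structure(
    list(pairs = pairs,
         mean_abs_matrix = mean_abs,
         max_off_diagonal = max(off),
         max_main_effect = max(diag(mean_abs)),
         relative_strength = if (max(diag(mean_abs)) > 0)
           max(off) / max(diag(mean_abs)) else 0),
    class = "interaction_scan"
  )
}

#' @export
print.interaction_scan <- function(x, ...) {
  cat("<interaction_scan> max |interaction| ", signif(x$max_off_diagonal, 4),
      " (", signif(100 * x$relative_strength, 3), "% of the strongest main effect)\n",
      sep = "")
  invisible(x)
}
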