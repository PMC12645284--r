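# Nested stratified cross-validation with joint featurisation + model tuning,
# classification metrics, and statistical comparison of configurations
# (Friedman test with Conover post-hoc and Holm adjustment).

#' The hyperparameter search grid
#'
#' Defaults reproduce the study grid: fingerprint length 2048/4096/8192 and
#' maximum path length 4/5/6, tuned jointly with either the random-forest
#' grid (100/200/500 trees, depth 2/4/6, 2/5/10 split candidates) or the
#' neural-network grid (hidden layers (8,0)/(16,0)/(8,4)/(16,8), 500/1000/1500
#' iterations).
#'
#' @param fingerprint list with `n_bits` and `max_path` vectors.
#' @param rf list with `n_trees`, `max_depth`, `mtry` vectors.
#' @param nn list with `hidden` (list of length-2 integer vectors) and
#'   `max_iter` vectors.
#' @return a `hyper_grid` object.
#' @export
hyper_grid <- function(fingerprint = list(n_bits = c(2048, 4096, 8192),
                                          max_path = c(4, 5, 6)),
                       rf = list(n_trees = c(100, 200, 500),
                                 max_depth = c(2, 4, 6),
                                 mtry = c(2, 5, 10)),
                       nn = list(hidden = list(c(8, 0), c(16, 0), c(8, 4), c(16, 8)),
                                 max_iter = c(500, 1000, 1500))) {
  structure(list(fingerprint = fingerprint, rf = rf, nn = nn),
            class = "hyper_grid")
}

# configs in grid-listing order (featurisation first, model parameters after;
# later values vary fastest) -- inner-loop accuracy ties go to the first
enumerate_configs <- function(grid, algorithm, features) {
  fps <- if (features == "fingerprint") {
    out <- list()
    for (nb in grid$fingerprint$n_bits)
      for (mp in grid$fingerprint$max_path)
        out[[length(out) + 1]] <- list(n_bits = nb, max_path = mp)
    out
  } else list(NULL)
  cfgs <- list()
  for (fp in fps) {
    if (algorithm == "rf") {
      for (nt in grid$rf$n_trees)
        for (md in grid$rf$max_depth)
          for (mt in grid$rf$mtry)
            cfgs[[length(cfgs) + 1]] <- list(fp = fp, model = list(n_trees = nt, max_depth = md, mtry = mt))
    } else {
      for (h in grid$nn$hidden)
        for (mi in grid$nn$max_iter)
          cfgs[[length(cfgs) + 1]] <- list(fp = fp, model = list(hidden = h, max_iter = mi))
    }
  }
  cfgs
}

#' Stratified fold assignment
#'
#' Shuffles within each class and deals samples round-robin, so per-fold
#' class counts differ from the global ratio by at most one sample.
#'
#' @param y binary labels.
#' @param k number of folds.
#' @return integer fold id per sample.
#' @export
make_stratified_folds <- function(y, k) {
  y <- as.integer(y)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      abort(sprintf("class %d has %d samples, fewer than %d folds", cls, length(idx), k),
            class = "polybiodeg_stratification_error")
    }
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Classification metrics from predicted probabilities
#'
#' Accuracy, precision, recall, F1 (at the given threshold), ROC-AUC and the
#' Brier score (mean squared difference between probability and outcome).
#' Precision is `NA` when nothing is predicted positive; ROC-AUC is `NA` when
#' only one class is present.
#'
#' @param y_true binary labels.
#' @param y_prob predicted probabilities of the positive class.
#' @param threshold classification threshold (default 0.5).
#' @return a one-row tibble.
#' @export
metrics <- function(y_true, y_prob, threshold = 0.5) {
  y <- as.integer(y_true)
  stopifnot(length(y) == length(y_prob), all(y_prob >= 0 & y_prob <= 1))
  pred <- as.integer(y_prob > threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  auc <- if (length(unique(y)) < 2) NA_real_ else {
    as.numeric(pROC::auc(pROC::roc(response = y, predictor = y_prob,
                                   levels = c(0, 1), direction = "<", quiet = TRUE)))
  }
  tibble(
    accuracy = mean(pred == y),
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    f1 = if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn),
    roc_auc = auc,
    brier = mean((y_prob - y)^2)
  )
}

fit_model <- function(algorithm, X, y, params, seed) {
  if (algorithm == "rf") {
    fit_rf(X, y, n_trees = params$n_trees, max_depth = params$max_depth,
           mtry = params$mtry, seed = seed)
  } else {
    mlp_fit(X, y, hidden = params$hidden, max_iter = params$max_iter, seed = seed)
  }
}

# memoised fingerprint matrices (path enumeration is a pure function of the
# SMILES set and the fingerprint configuration)
the_fp_cache <- new.env(parent = emptyenv())
the_fp_cache$keys <- character(0)
the_fp_cache$vals <- list()

fingerprint_matrix_cached <- function(smiles, cfg) {
  key <- paste(cfg$n_bits, cfg$max_path, paste(smiles, collapse = "\r"), sep = "\r\r")
  hit <- match(key, the_fp_cache$keys)
  if (!is.na(hit)) return(the_fp_cache$vals[[hit]])
  val <- fingerprint(smiles, cfg)$matrix
  the_fp_cache$keys <- c(the_fp_cache$keys, key)
  the_fp_cache$vals <- c(the_fp_cache$vals, list(val))
  val
}

prepare_feature_sets <- function(smiles, features, grid, extra_features = NULL) {
  add_extra <- function(m) {
    if (is.null(extra_features)) return(m)
    extra <- as.matrix(extra_features)
    if (is.null(colnames(extra))) colnames(extra) <- paste0("extra", seq_len(ncol(extra)))
    cbind(m, extra)
  }
  if (features == "fingerprint") {
    sets <- list()
    for (nb in grid$fingerprint$n_bits)
      for (mp in grid$fingerprint$max_path)
        sets[[paste(nb, mp)]] <- add_extra(
          fingerprint_matrix_cached(smiles, fp_config(nb, mp)))
    sets
  } else {
    list(descriptor = add_extra(descriptors(smiles)$matrix))
  }
}

config_matrix_key <- function(cfg) {
  if (is.null(cfg$fp)) "descriptor" else paste(cfg$fp$n_bits, cfg$fp$max_path)
}

#' Nested stratified cross-validation with joint featurisation tuning
#'
#' The outer loop estimates generalisation performance; the inner loop tunes
#' featurisation and model hyperparameters jointly by grid search, selecting
#' the configuration with the highest inner-fold accuracy (ties broken by
#' grid order). Zero-variance filtering of descriptors is learned on each
#' training fold and applied, not re-learned, to the corresponding test fold
#' (set `per_fold_filter = FALSE` for a single whole-dataset filter).
#'
#' @param data tibble with a `trimer_smiles` (or `smiles`) column and a
#'   logical/0-1 `label` column.
#' @param algorithm `"rf"` or `"nn"`.
#' @param features `"fingerprint"` or `"descriptor"`.
#' @param grid a [hyper_grid()].
#' @param k_outer,k_inner fold counts (default 5/5).
#' @param seed integer seed driving fold assignment and every model fit.
#' @param extra_features optional numeric matrix of per-sample columns to
#'   append to every candidate feature matrix (used by the chained model).
#' @param per_fold_filter learn the descriptor variance mask per training
#'   fold (default) instead of once on the full dataset.
#' @return a `cv_result` object; see [tidy()] and [glance()] methods.
#' @export
nested_cv <- function(data, algorithm = c("rf", "nn"),
                      features = c("fingerprint", "descriptor"),
                      grid = hyper_grid(), k_outer = 5, k_inner = 5, seed = 1,
                      extra_features = NULL, per_fold_filter = TRUE) {
  algorithm <- match.arg(algorithm)
  features <- match.arg(features)
  data <- as_tibble(data)
  smiles <- smiles_column(data)
  y <- as.integer(data$label)
  stopifnot(all(y %in% 0:1))
  if (min(table(y)) < 2) {
    abort("need at least two samples per class", class = "polybiodeg_contract_error")
  }
  configs <- enumerate_configs(grid, algorithm, features)
  if (length(configs) == 0) abort("empty hyperparameter grid",
                                  class = "polybiodeg_contract_error")
  sets <- prepare_feature_sets(smiles, features, grid, extra_features)

  set.seed(seed)
  outer_fold <- make_stratified_folds(y, k_outer)
  inner_seed_pool <- sample.int(.Machine$integer.max, k_outer)
  n_fits <- k_outer * (length(configs) * k_inner + 1)
  fit_seeds <- sample.int(.Machine$integer.max, n_fits)
  fit_i <- 0L

  fold_rows <- list()
  pred_rows <- list()
  for (of in seq_len(k_outer)) {
    tr_idx <- which(outer_fold != of)
    te_idx <- which(outer_fold == of)
    set.seed(inner_seed_pool[of])
    inner_fold <- make_stratified_folds(y[tr_idx], k_inner)

    # per-(matrix, inner-split) training data, shared across model configs;
    # the zero-variance mask is learned on the training rows and applied,
    # never re-learned, on the corresponding held-out rows
    masks <- list()
    get_xy <- function(key, idx_tr, idx_te) {
      m <- sets[[key]]
      if (per_fold_filter) {
        mkey <- paste(key, paste(idx_tr, collapse = ","))
        if (is.null(masks[[mkey]])) {
          masks[[mkey]] <<- matrixStats_colVars(m[idx_tr, , drop = FALSE]) > 0
        }
        keep <- masks[[mkey]]
        list(tr = m[idx_tr, keep, drop = FALSE], te = m[idx_te, keep, drop = FALSE])
      } else {
        list(tr = m[idx_tr, , drop = FALSE], te = m[idx_te, , drop = FALSE])
      }
    }

    inner_acc <- numeric(length(configs))
    if (length(configs) == 1) inner_acc <- NA_real_  # nothing to select
    for (inf in if (length(configs) == 1) integer(0) else seq_len(k_inner)) {
      it <- tr_idx[inner_fold != inf]
      iv <- tr_idx[inner_fold == inf]
      xy_by_key <- list()
      for (ci in seq_along(configs)) {
        cfg <- configs[[ci]]
        key <- config_matrix_key(cfg)
        if (is.null(xy_by_key[[key]])) xy_by_key[[key]] <- get_xy(key, it, iv)
        xy <- xy_by_key[[key]]
        fit_i <- fit_i + 1L
        fit <- fit_model(algorithm, xy$tr, y[it], cfg$model, fit_seeds[fit_i])
        p <- predict_prob(fit, xy$te)
        inner_acc[ci] <- inner_acc[ci] + mean((p > 0.5) == (y[iv] == 1)) / k_inner
      }
    }
    best <- if (length(configs) == 1) 1L else which.max(inner_acc)  # first max wins on ties
    cfg <- configs[[best]]
    xy <- get_xy(config_matrix_key(cfg), tr_idx, te_idx)
    fit_i <- fit_i + 1L
    fit <- fit_model(algorithm, xy$tr, y[tr_idx], cfg$model, fit_seeds[fit_i])
    p <- predict_prob(fit, xy$te)
    fold_rows[[of]] <- bind_cols(
      tibble(fold = of),
      metrics(y[te_idx], p),
      tibble(chosen = list(cfg), inner_accuracy = inner_acc[best])
    )
    pred_rows[[of]] <- tibble(idx = te_idx, fold = of, prob = p, label = y[te_idx])
  }
  folds <- bind_rows(fold_rows)
  preds <- bind_rows(pred_rows) %>% arrange(.data$idx)
  stopifnot(identical(preds$idx, seq_along(y)))  # each sample predicted once
  structure(
    list(folds = folds, predictions = preds, algorithm = algorithm,
         features = features, seed = seed, grid = grid,
         outer_fold = outer_fold),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  g <- glance(x)
  cat("<cv_result> ", x$algorithm, " + ", x$features, ", ", nrow(x$folds),
      " outer folds (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  accuracy %.3f +/- %.3f, F1 %.3f, ROC-AUC %.3f, Brier %.3f\n",
              g$accuracy, g$accuracy_sd, g$f1, g$roc_auc, g$brier))
  invisible(x)
}

# ---------------------------------------------------------------------------
# statistical comparison of configurations

#' Compare model configurations across shared cross-validation folds
#'
#' Applies the Friedman test to the fold-by-configuration score matrix; the
#' Conover post-hoc test (on within-fold rank sums, t-distributed with
#' (b-1)(k-1) degrees of freedom) provides pairwise p-values, adjusted with
#' Holm's step-down procedure.
#'
#' @param results named list of `cv_result` objects (>= 3) sharing the fold
#'   structure, or a numeric folds-by-configurations matrix.
#' @param metric which per-fold metric to compare (default `"accuracy"`).
#' @return a `comparison_report` with elements `friedman_statistic`,
#'   `friedman_p`, and `pairwise` (tibble of raw and Holm-adjusted p-values).
#' @export
compare_configs <- function(results, metric = "accuracy") {
  if (is.matrix(results)) {
    scores <- results
    if (is.null(colnames(scores))) colnames(scores) <- paste0("config", seq_len(ncol(scores)))
  } else {
    if (length(results) < 3) abort("need at least 3 configurations",
                                   class = "polybiodeg_contract_error")
    nf <- vapply(results, function(r) nrow(r$folds), integer(1))
    if (length(unique(nf)) != 1) {
      abort("configurations have mismatched fold counts",
            class = "polybiodeg_pairing_error")
    }
    scores <- vapply(results, function(r) r$folds[[metric]], numeric(nf[1]))
    if (is.null(colnames(scores)) || any(!nzchar(colnames(scores)))) {
      colnames(scores) <- paste0("config", seq_len(ncol(scores)))
    }
  }
  b <- nrow(scores); k <- ncol(scores)
  r <- t(apply(scores, 1, rank))
  if (all(apply(r, 2, function(col) length(unique(col)) == 1)) &&
      length(unique(r[1, ])) == 1) {
    # every fold ranks all configurations identically equal: no evidence
    fr_stat <- 0; fr_p <- 1
  } else {
    ft <- friedman.test(scores)
    fr_stat <- unname(ft$statistic); fr_p <- ft$p.value
    if (is.nan(fr_stat)) { fr_stat <- 0; fr_p <- 1 }
  }
  Rj <- colSums(r)
  A1 <- sum(r^2)
  denom <- 2 * (b * A1 - sum(Rj^2)) / ((b - 1) * (k - 1))
  pairs <- utils::combn(k, 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(pi) {
    i <- pairs[1, pi]; j <- pairs[2, pi]
    tval <- if (denom <= 0) 0 else unname(abs(Rj[i] - Rj[j])) / sqrt(denom)
    tibble(config1 = colnames(scores)[i], config2 = colnames(scores)[j],
           statistic = tval,
           p_value = if (denom <= 0) 1 else 2 * pt(-abs(tval), df = (b - 1) * (k - 1)))
  })
  pw$p_adjusted <- p.adjust(pw$p_value, method = "holm")
  structure(
    list(metric = metric, n_folds = b, configurations = colnames(scores),
         friedman_statistic = fr_stat, friedman_p = fr_p, pairwise = pw,
         scores = scores),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> metric:", x$metric, "\n")
  cat(sprintf("  Friedman chi-squared = %.3f, p = %.4f (%d configs, %d folds)\n",
              x$friedman_statistic, x$friedman_p, length(x$configurations), x$n_folds))
  print(x$pairwise)
  invisible(x)
}
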