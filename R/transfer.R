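# Integration of an external source model: the chained model (source
# probability appended as a target feature) and three-phase neural-network
# fine-tuning (pre-train on source, retrain the output layer on target, one
# low-learning-rate full-network pass).

#' Chain a source model into the target benchmark
#'
#' A random forest is tuned (plain stratified 5-fold grid search) and fitted
#' once on the full source dataset; its predicted probability on each target
#' polymer is appended as one extra feature column, and the augmented target
#' dataset is evaluated with the same nested-CV protocol as the benchmark.
#' Source and target share the hashed fingerprint bit space by construction.
#'
#' @param source,target library tibbles with `trimer_smiles` and `label`.
#' @param grid a [hyper_grid()].
#' @param seed integer seed.
#' @param source_prob optional probability vector overriding the source
#'   model's predictions on the target (used for oracle/null experiments).
#' @return a `chained_model`: list with `source_model`, `source_config`,
#'   `source_prob`, `cv` (a `cv_result` on the augmented target), and the
#'   augmented feature count check.
#' @export
chain <- function(source, target, grid = hyper_grid(), seed = 1,
                  source_prob = NULL) {
  target <- as_tibble(target)
  src_model <- NULL; src_cfg <- NULL
  if (is.null(source_prob)) {
    source <- as_tibble(source)
    src_cfg <- select_config(source, "rf", "fingerprint", grid, seed = seed)
    src_fp_cfg <- fp_config(src_cfg$fp$n_bits, src_cfg$fp$max_path)
    Xs <- fingerprint(source, src_fp_cfg)$matrix
    keep <- matrixStats_colVars(Xs) > 0
    set.seed(seed)
    src_model <- fit_rf(Xs[, keep, drop = FALSE], as.integer(source$label),
                        n_trees = src_cfg$model$n_trees,
                        max_depth = src_cfg$model$max_depth,
                        mtry = src_cfg$model$mtry,
                        seed = sample.int(.Machine$integer.max, 1))
    Xt <- fingerprint(target, src_fp_cfg)$matrix[, keep, drop = FALSE]
    source_prob <- predict_prob(src_model, Xt)
  } else {
    stopifnot(length(source_prob) == nrow(target))
  }
  extra <- matrix(source_prob, ncol = 1, dimnames = list(NULL, "source_prob"))
  cv <- nested_cv(target, "rf", "fingerprint", grid = grid, seed = seed,
                  extra_features = extra)
  structure(
    list(source_model = src_model, source_config = src_cfg,
         source_prob = source_prob, cv = cv, grid = grid, seed = seed,
         target = target),
    class = "chained_model"
  )
}

#' @export
print.chained_model <- function(x, ...) {
  cat("<chained_model> source probability appended to target features\n")
  print(x$cv)
  invisible(x)
}

#' Rank of the chained source-probability feature
#'
#' Refits the tuned chained configuration on the full target dataset and
#' ranks all features by mean absolute Shapley value; returns the appended
#' source-probability column's rank (1 = most important).
#'
#' @param chained a `chained_model`.
#' @param seed integer seed for the refit.
#' @return list with `rank`, `n_features` and the full `feature_report`.
#' @export
importance_of_chain_feature <- function(chained, seed = chained$seed) {
  target <- chained$target
  extra <- matrix(chained$source_prob, ncol = 1,
                  dimnames = list(NULL, "source_prob"))
  cfg <- select_config(target, "rf", "fingerprint", chained$grid, seed = seed,
                       extra_features = extra)
  X <- cbind(fingerprint(target, fp_config(cfg$fp$n_bits, cfg$fp$max_path))$matrix,
             extra)
  keep <- matrixStats_colVars(X) > 0
  keep["source_prob" == colnames(X)] <- TRUE  # keep even a constant source column
  set.seed(seed)
  fit <- fit_rf(X[, keep, drop = FALSE], as.integer(target$label),
                n_trees = cfg$model$n_trees, max_depth = cfg$model$max_depth,
                mtry = cfg$model$mtry, seed = sample.int(.Machine$integer.max, 1))
  attr <- shap_values(fit)
  rep <- feature_report(attr)
  list(rank = which(rep$feature == "source_prob"),
       n_features = nrow(rep), report = rep,
       shap = attr)
}

#' Fine-tuning plan for cross-dataset neural-network transfer
#'
#' @param hidden architecture (from the tuning grid), identical across all
#'   phases.
#' @param fp fingerprint configuration shared by source and target.
#' @param pretrain_max_iter optimiser iterations for source pre-training.
#' @param retrain_max_iter iterations for target output-layer retraining.
#' @param final_epochs full-network gradient steps in the last phase
#'   (default 1).
#' @param final_lr learning rate of the final pass (default 1e-4).
#' @return a `finetune_plan` object.
#' @export
finetune_plan <- function(hidden = c(16, 8), fp = fp_config(2048, 6),
                          pretrain_max_iter = 1000, retrain_max_iter = 500,
                          final_epochs = 1, final_lr = 1e-4) {
  structure(list(hidden = hidden, fp = fp,
                 pretrain_max_iter = pretrain_max_iter,
                 retrain_max_iter = retrain_max_iter,
                 final_epochs = final_epochs, final_lr = final_lr),
            class = "finetune_plan")
}

# retrain only the output layer (final linear layer) on new data
mlp_retrain_output <- function(model, X, y, max_iter) {
  if (max_iter <= 0) return(model)
  y <- as.integer(y)
  Zs <- mlp_transform(model, X)
  w <- mlp_weights(model)
  a <- Zs
  for (l in seq_along(w$Ws)) {
    a <- tanh(a %*% w$Ws[[l]] + matrix(w$bs[[l]], nrow(a), length(w$bs[[l]]), byrow = TRUE))
  }
  par0 <- c(as.numeric(w$wout), w$bout)
  nh <- ncol(a)
  loss_grad <- function(par) {
    eta <- drop(a %*% par[seq_len(nh)] + par[nh + 1])
    p <- 1 / (1 + exp(-eta))
    pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    d <- (p - y) / length(y)
    list(loss = -mean(y * log(pc) + (1 - y) * log(1 - pc)),
         grad = c(drop(t(a) %*% d), sum(d)))
  }
  opt <- optim(par0, function(p) loss_grad(p)$loss, function(p) loss_grad(p)$grad,
               method = "L-BFGS-B", control = list(maxit = max_iter))
  m <- mlp_unpack(model$par, model$dims)
  m$wout <- matrix(opt$par[seq_len(nh)], ncol = 1)
  m$bout <- matrix(opt$par[nh + 1], 1, 1)
  model$par <- mlp_pack(m[model$layer_names])
  model
}

# full-network plain gradient steps at a low learning rate
mlp_full_steps <- function(model, X, y, lr, epochs) {
  if (epochs <= 0) return(model)
  y <- as.integer(y)
  Zs <- mlp_transform(model, X)
  par <- model$par
  for (e in seq_len(epochs)) {
    g <- mlp_loss_grad(par, Zs, y, model$dims, model$layer_names)$grad
    par <- par - lr * g
  }
  model$par <- par
  model
}

#' Fine-tune a source-pretrained network on a target dataset
#'
#' Phase 1 pre-trains the network on the full source dataset; then, within
#' each outer stratified CV fold of the target, phase 2 retrains the output
#' layer on the target training fold and phase 3 runs `final_epochs`
#' full-network gradient steps at a low learning rate. The architecture is
#' identical across all phases.
#'
#' @param source,target library tibbles with `trimer_smiles` and `label`.
#' @param plan a [finetune_plan()].
#' @param seed integer seed.
#' @param k_outer outer folds on the target (default 5).
#' @return a `cv_result` over the target outer folds, with the pretrained
#'   model attached as attribute `pretrained`.
#' @export
finetune <- function(source, target, plan = finetune_plan(), seed = 1,
                     k_outer = 5) {
  source <- as_tibble(source); target <- as_tibble(target)
  ys <- as.integer(source$label); yt <- as.integer(target$label)
  Xs <- fingerprint(source, plan$fp)$matrix
  Xt <- fingerprint(target, plan$fp)$matrix
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2 + k_outer)
  base <- mlp_fit(Xs, ys, hidden = plan$hidden, max_iter = plan$pretrain_max_iter,
                  seed = seeds[1])
  if (any(!is.finite(base$loss))) {
    abort(paste0("pretraining diverged (seed ", seeds[1], ")"),
          class = "polybiodeg_training_error")
  }
  set.seed(seeds[2])
  fold <- make_stratified_folds(yt, k_outer)
  fold_rows <- list(); pred_rows <- list()
  for (of in seq_len(k_outer)) {
    tr <- which(fold != of); te <- which(fold == of)
    m <- base
    m <- mlp_retrain_output(m, Xt[tr, , drop = FALSE], yt[tr], plan$retrain_max_iter)
    m <- mlp_full_steps(m, Xt[tr, , drop = FALSE], yt[tr], plan$final_lr,
                        plan$final_epochs)
    p <- predict_prob(m, Xt[te, , drop = FALSE])
    if (any(!is.finite(p))) {
      abort(paste0("fine-tuning diverged (seed ", seeds[2 + of], ")"),
            class = "polybiodeg_training_error")
    }
    fold_rows[[of]] <- bind_cols(tibble(fold = of), metrics(yt[te], p),
                                 tibble(chosen = list(plan), inner_accuracy = NA_real_))
    pred_rows[[of]] <- tibble(idx = te, fold = of, prob = p, label = yt[te])
  }
  res <- structure(
    list(folds = bind_rows(fold_rows),
         predictions = bind_rows(pred_rows) %>% arrange(.data$idx),
         algorithm = "nn", features = "fingerprint", seed = seed,
         grid = NULL, outer_fold = fold),
    class = "cv_result"
  )
  attr(res, "pretrained") <- base
  res
}
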