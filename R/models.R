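# Model fitting backends: a random-forest wrapper (ranger) that retains what
# the Shapley explainer needs, and a small feed-forward neural network
# classifier trained by L-BFGS.

#' Fit a probability random forest
#'
#' @param X numeric sample-by-feature matrix.
#' @param y binary labels (logical or 0/1).
#' @param n_trees,max_depth,mtry forest hyperparameters (the tuning grid uses
#'   100/200/500 trees, depth 2/4/6, 2/5/10 candidate features per split).
#' @param seed integer seed for bootstrap and split sampling.
#' @return a `polybiodeg_rf` object.
#' @export
fit_rf <- function(X, y, n_trees = 200, max_depth = 6, mtry = 10, seed = 1) {
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), nrow(X) == length(y))
  mtry <- min(mtry, ncol(X))
  fit <- ranger::ranger(
    x = X, y = factor(y, levels = c(0, 1)),
    num.trees = n_trees, max.depth = max_depth, mtry = mtry,
    probability = TRUE, num.threads = 1, verbose = FALSE, seed = seed
  )
  structure(
    list(fit = fit, feature_names = colnames(X), X_train = X, y_train = y,
         params = list(n_trees = n_trees, max_depth = max_depth, mtry = mtry),
         seed = seed),
    class = "polybiodeg_rf"
  )
}

#' Predicted probability of the positive class
#' @param model a fitted `polybiodeg_rf` or `polybiodeg_mlp`.
#' @param X feature matrix in the training feature space.
#' @return numeric vector of probabilities.
#' @export
predict_prob <- function(model, X) UseMethod("predict_prob")

#' @export
predict_prob.polybiodeg_rf <- function(model, X) {
  if (ncol(X) != length(model$feature_names)) {
    abort("feature-space mismatch between model and data",
          class = "polybiodeg_contract_error")
  }
  colnames(X) <- model$feature_names
  pr <- predict(model$fit, data = X, num.threads = 1, verbose = FALSE)$predictions
  unname(pr[, "1"])
}

# per-tree arrays for the Shapley kernels: left/right children (0-based, -1
# at leaves mapped to self), split feature (0-based, -1 leaf), threshold,
# leaf value (probability of class 1), training cover per node.
rf_forest_arrays <- function(model) {
  if (!is.null(model$forest_arrays)) return(model$forest_arrays)
  nt <- model$fit$num.trees
  Xtr <- model$X_train
  storage.mode(Xtr) <- "double"
  trees <- vector("list", nt)
  for (t in seq_len(nt)) {
    ti <- ranger::treeInfo(model$fit, t)
    leaf <- ti$terminal
    left <- ifelse(leaf, 0L, ti$leftChild)
    right <- ifelse(leaf, 0L, ti$rightChild)
    feature <- ifelse(leaf, -1L, ti$splitvarID)
    threshold <- ifelse(leaf, 0, ti$splitval)
    value <- ifelse(leaf, ti$pred.1, 0)
    cover <- tree_cover_cpp(as.integer(left), as.integer(right),
                            as.integer(feature), as.numeric(threshold), Xtr)
    trees[[t]] <- list(left = as.integer(left), right = as.integer(right),
                       feature = as.integer(feature),
                       threshold = as.numeric(threshold),
                       value = as.numeric(value), cover = as.numeric(cover))
  }
  trees
}

# ---------------------------------------------------------------------------
# Minimal multilayer perceptron: tanh hidden layer(s), sigmoid output,
# mean log-loss, full-batch L-BFGS. For wide fingerprint inputs (p >> n) the
# first layer is parameterised in the span of the training rows by mapping
# inputs to kernel features k(x) = X_train x; this is an exact
# reparameterisation of the functions reachable by training (gradients of the
# first layer always lie in that span) and keeps fitting cost independent of
# the bit-space size.

mlp_pack <- function(w) unlist(w, use.names = FALSE)

mlp_unpack <- function(par, dims) {
  out <- list()
  pos <- 1
  for (nm in names(dims)) {
    d <- dims[[nm]]
    len <- prod(d)
    out[[nm]] <- matrix(par[pos:(pos + len - 1)], d[1], d[2])
    pos <- pos + len
  }
  out
}

mlp_forward <- function(w, X, hidden) {
  a <- X
  zs <- list(); as_ <- list(X)
  n_hidden <- length(w$Ws)
  for (l in seq_len(n_hidden)) {
    z <- a %*% w$Ws[[l]] + matrix(w$bs[[l]], nrow(a), length(w$bs[[l]]), byrow = TRUE)
    a <- tanh(z)
    zs[[l]] <- z; as_[[l + 1]] <- a
  }
  eta <- drop(a %*% w$wout + w$bout)
  p <- 1 / (1 + exp(-eta))
  list(p = p, eta = eta, zs = zs, as_ = as_)
}

mlp_loss_grad <- function(par, X, y, dims, layer_names) {
  n <- nrow(X)
  m <- mlp_unpack(par, dims)
  w <- list(Ws = m[grep("^W", layer_names, value = TRUE)],
            bs = lapply(m[grep("^b[0-9]", layer_names, value = TRUE)], drop),
            wout = m$wout, bout = drop(m$bout))
  fw <- mlp_forward(w, X, NULL)
  p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  # backprop
  d_eta <- (fw$p - y) / n                      # n
  g <- list()
  nh <- length(w$Ws)
  a_last <- fw$as_[[nh + 1]]
  g$wout <- t(a_last) %*% d_eta
  g$bout <- matrix(sum(d_eta), 1, 1)
  delta <- outer(d_eta, drop(w$wout)) * (1 - fw$as_[[nh + 1]]^2)  # n x h_last
  for (l in nh:1) {
    g[[paste0("W", l)]] <- t(fw$as_[[l]]) %*% delta
    g[[paste0("b", l)]] <- matrix(colSums(delta), 1)
    if (l > 1) {
      delta <- (delta %*% t(w$Ws[[l]])) * (1 - fw$as_[[l]]^2)
    }
  }
  grad <- unlist(lapply(layer_names, function(nm) g[[nm]]), use.names = FALSE)
  list(loss = loss, grad = grad)
}

#' Fit a small feed-forward neural-network classifier
#'
#' @param X numeric feature matrix.
#' @param y binary labels.
#' @param hidden hidden layer sizes as `c(h1, h2)`; `h2 = 0` means a single
#'   hidden layer (grid: (8,0), (16,0), (8,4), (16,8)).
#' @param max_iter maximum optimiser iterations (grid: 500/1000/1500).
#' @param seed integer seed for weight initialisation.
#' @param kernelise `"auto"` (kernel features when p > 2n), `TRUE` or `FALSE`.
#' @return a `polybiodeg_mlp` object.
#' @export
mlp_fit <- function(X, y, hidden = c(8, 0), max_iter = 500, seed = 1,
                    kernelise = "auto") {
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), nrow(X) == length(y))
  use_kernel <- if (identical(kernelise, "auto")) ncol(X) > 2 * nrow(X) else isTRUE(kernelise)
  kernel_ref <- NULL
  Z <- X
  if (use_kernel) {
    kernel_ref <- X
    Z <- X %*% t(kernel_ref)
  }
  ctr <- colMeans(Z)
  scl <- apply(Z, 2, sd)
  scl[scl == 0] <- 1
  Zs <- scale(Z, center = ctr, scale = scl)
  sizes <- c(ncol(Zs), hidden[hidden > 0])
  nh <- length(sizes) - 1
  set.seed(seed)
  dims <- list()
  layer_names <- character(0)
  init <- list()
  for (l in seq_len(nh)) {
    dims[[paste0("W", l)]] <- c(sizes[l], sizes[l + 1])
    dims[[paste0("b", l)]] <- c(1, sizes[l + 1])
    init[[paste0("W", l)]] <- matrix(rnorm(sizes[l] * sizes[l + 1],
                                           sd = sqrt(2 / (sizes[l] + sizes[l + 1]))),
                                     sizes[l], sizes[l + 1])
    init[[paste0("b", l)]] <- matrix(0, 1, sizes[l + 1])
  }
  dims$wout <- c(sizes[nh + 1], 1)
  dims$bout <- c(1, 1)
  init$wout <- matrix(rnorm(sizes[nh + 1], sd = sqrt(2 / sizes[nh + 1])), ncol = 1)
  init$bout <- matrix(0, 1, 1)
  layer_names <- names(dims)
  par0 <- mlp_pack(init[layer_names])
  fn <- function(par) mlp_loss_grad(par, Zs, y, dims, layer_names)$loss
  gr <- function(par) mlp_loss_grad(par, Zs, y, dims, layer_names)$grad
  opt <- optim(par0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = max_iter))
  structure(
    list(par = opt$par, dims = dims, layer_names = layer_names,
         hidden = hidden, center = ctr, scale = scl,
         kernel_ref = kernel_ref, loss = opt$value, seed = seed,
         max_iter = max_iter),
    class = "polybiodeg_mlp"
  )
}

mlp_weights <- function(model) {
  m <- mlp_unpack(model$par, model$dims)
  list(Ws = m[grep("^W", model$layer_names, value = TRUE)],
       bs = lapply(m[grep("^b[0-9]", model$layer_names, value = TRUE)], drop),
       wout = m$wout, bout = drop(m$bout))
}

mlp_transform <- function(model, X) {
  Z <- if (!is.null(model$kernel_ref)) X %*% t(model$kernel_ref) else X
  scale(Z, center = model$center, scale = model$scale)
}

#' @export
predict_prob.polybiodeg_mlp <- function(model, X) {
  Zs <- mlp_transform(model, X)
  unname(mlp_forward(mlp_weights(model), Zs, NULL)$p)
}
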