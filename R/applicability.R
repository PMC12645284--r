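# Three-tier applicability domain for fingerprinted polymers:
#   validity    - bounding box over binary features (only seen bits, and all
#                 universally-present bits)
#   reliability - mean Tanimoto similarity to the k nearest training samples,
#                 binned into low/mid/high similarity groups with
#                 similarity-resolved calibration curves
#   decidability - distance of the predicted probability from 0.5

#' Applicability-domain configuration
#'
#' @param k_neighbors neighbours used for the reliability score (default 5).
#' @param similarity_thresholds ordered pair splitting reliability scores
#'   into low (< t1), mid ([t1, t2]) and high (> t2) groups (default 0.8, 0.9).
#' @param min_bin_size minimum samples per calibration point (default 4).
#' @param decidability_delta probability half-width around 0.5 inside which a
#'   prediction is rejected as undecidable (default 0.1; the appropriate
#'   value is use-case dependent).
#' @return an `ad_config` object.
#' @export
ad_config <- function(k_neighbors = 5, similarity_thresholds = c(0.8, 0.9),
                      min_bin_size = 4, decidability_delta = 0.1) {
  stopifnot(k_neighbors >= 1, length(similarity_thresholds) == 2,
            all(similarity_thresholds > 0), all(similarity_thresholds < 1),
            similarity_thresholds[1] < similarity_thresholds[2],
            min_bin_size >= 1, decidability_delta >= 0, decidability_delta < 0.5)
  structure(list(k_neighbors = k_neighbors,
                 similarity_thresholds = similarity_thresholds,
                 min_bin_size = min_bin_size,
                 decidability_delta = decidability_delta),
            class = "ad_config")
}

#' Tanimoto similarity of two binary feature vectors
#'
#' `|a & b| / |a | b|`; two all-zero vectors score 1 by convention (identical
#' empty substructure sets; unreachable for real trimers).
#'
#' @param a,b binary (0/1) vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# pairwise Tanimoto between rows of two binary matrices
tanimoto_matrix <- function(A, B) {
  A <- matrix(as.numeric(A > 0), nrow(A)); B <- matrix(as.numeric(B > 0), nrow(B))
  inter <- tcrossprod(A, B)
  ra <- rowSums(A); rb <- rowSums(B)
  uni <- outer(ra, rb, "+") - inter
  out <- ifelse(uni == 0, 1, inter / uni)
  out
}

#' Fit the applicability domain of a training set
#'
#' @param train_matrix binary training fingerprint matrix.
#' @param cfg an [ad_config()].
#' @return an `ad_domain` storing the observed-bit union, the
#'   universally-present bit set, the training matrix and the configuration.
#' @export
fit_ad <- function(train_matrix, cfg = ad_config()) {
  m <- as.matrix(train_matrix)
  structure(
    list(union_bits = colSums(m > 0) > 0,
         core_bits = colSums(m > 0) == nrow(m),
         train = m, cfg = cfg),
    class = "ad_domain"
  )
}

#' Bounding-box validity check
#'
#' A sample is inside the validity domain iff it contains only features
#' observed during training and omits no feature present across the entire
#' training set.
#'
#' @param x binary sample vector or matrix (rows = samples) in the training
#'   bit space.
#' @param ad an `ad_domain` (or binary training matrix).
#' @return logical vector, one element per sample.
#' @export
validity_check <- function(x, ad) {
  if (!inherits(ad, "ad_domain")) ad <- fit_ad(ad)
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != length(ad$union_bits)) {
    abort("bit-space dimension mismatch", class = "polybiodeg_contract_error")
  }
  xb <- x > 0
  only_seen <- !apply(xb & !matrix(ad$union_bits, nrow(x), ncol(x), byrow = TRUE), 1, any)
  has_core <- !apply(!xb & matrix(ad$core_bits, nrow(x), ncol(x), byrow = TRUE), 1, any)
  unname(only_seen & has_core)
}

#' Reliability scores: mean Tanimoto to the k nearest training neighbours
#'
#' In `"loo"` mode every sample of `x` is scored against the remaining
#' samples (leave-one-out); in `"train_vs_test"` mode rows of `x` are scored
#' against `train`. Ties at the k-th neighbour resolve to the
#' lowest-indexed sample.
#'
#' @param x binary fingerprint matrix to score.
#' @param cfg an [ad_config()].
#' @param mode `"loo"` or `"train_vs_test"`.
#' @param train training matrix (required for `"train_vs_test"`).
#' @return tibble with `reliability_score` and `similarity_group`
#'   (`low`/`mid`/`high`).
#' @export
reliability_scores <- function(x, cfg = ad_config(), mode = c("loo", "train_vs_test"),
                               train = NULL) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  k <- cfg$k_neighbors
  if (mode == "loo") {
    if (nrow(x) < k + 1) {
      abort(sprintf("leave-one-out reliability needs at least %d samples", k + 1),
            class = "polybiodeg_contract_error")
    }
    sims <- tanimoto_matrix(x, x)
    diag(sims) <- -Inf
  } else {
    if (is.null(train)) abort("train matrix required", class = "polybiodeg_contract_error")
    if (nrow(train) < k) abort("training set smaller than k",
                               class = "polybiodeg_contract_error")
    sims <- tanimoto_matrix(x, as.matrix(train))
  }
  score <- apply(sims, 1, function(s) mean(sort(s, decreasing = TRUE)[seq_len(min(k, sum(is.finite(s))))]))
  t1 <- cfg$similarity_thresholds[1]; t2 <- cfg$similarity_thresholds[2]
  group <- ifelse(score < t1, "low", ifelse(score > t2, "high", "mid"))
  tibble(reliability_score = unname(score),
         similarity_group = factor(group, levels = c("low", "mid", "high")))
}

#' Similarity-resolved calibration curves
#'
#' Within each similarity group, held-out predicted probabilities are sorted
#' and cut into equal-count bins of at least `min_bin_size` samples (the last
#' bin absorbs the remainder); each bin contributes one (mean predicted
#' probability, observed positive frequency) point. Groups smaller than
#' `min_bin_size` are skipped with a warning.
#'
#' @param prob held-out predicted probabilities (never resubstitution).
#' @param label binary outcomes.
#' @param group similarity group per sample (factor from
#'   [reliability_scores()]).
#' @param cfg an [ad_config()].
#' @return a `calibration_set` tibble: `similarity_group`, `bin`,
#'   `mean_prob`, `obs_freq`, `n`.
#' @export
calibration_curves <- function(prob, label, group, cfg = ad_config()) {
  stopifnot(length(prob) == length(label), length(prob) == length(group))
  label <- as.integer(label)
  out <- list()
  for (g in levels(factor(group))) {
    idx <- which(group == g)
    if (length(idx) < cfg$min_bin_size) {
      warn(paste0("similarity group '", g, "' has fewer than ", cfg$min_bin_size,
                  " samples; skipped"))
      next
    }
    ord <- idx[order(prob[idx])]
    n_bins <- max(1, length(ord) %/% cfg$min_bin_size)
    sizes <- rep(length(ord) %/% n_bins, n_bins)
    if (n_bins > 0) sizes[n_bins] <- sizes[n_bins] + length(ord) %% n_bins
    start <- cumsum(c(1, head(sizes, -1)))
    for (b in seq_len(n_bins)) {
      sel <- ord[start[b]:(start[b] + sizes[b] - 1)]
      out[[length(out) + 1]] <- tibble(
        similarity_group = g, bin = b,
        mean_prob = mean(prob[sel]), obs_freq = mean(label[sel]), n = length(sel)
      )
    }
  }
  res <- if (length(out) == 0) {
    tibble(similarity_group = character(0), bin = integer(0),
           mean_prob = numeric(0), obs_freq = numeric(0), n = integer(0))
  } else bind_rows(out)
  class(res) <- c("calibration_set", class(res))
  res
}

#' Gate predictions through the applicability domain
#'
#' Gates are applied in sequence -- validity, then reliability (the low
#' similarity group is rejected), then decidability (probabilities within
#' `decidability_delta` of 0.5 are rejected) -- and the verdict records the
#' first failing gate.
#'
#' @param prob predicted probability per sample.
#' @param x binary fingerprint matrix of the samples.
#' @param ad a fitted `ad_domain`.
#' @return an `ad_report` tibble: `prob`, `in_validity`, `reliability_score`,
#'   `similarity_group`, `decidable`, `verdict`.
#' @export
gate <- function(prob, x, ad) {
  stopifnot(inherits(ad, "ad_domain"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  cfg <- ad$cfg
  valid <- validity_check(x, ad)
  rel <- reliability_scores(x, cfg, mode = "train_vs_test", train = ad$train)
  decidable <- abs(prob - 0.5) > cfg$decidability_delta
  verdict <- ifelse(!valid, "reject:validity",
             ifelse(rel$similarity_group == "low", "reject:reliability",
             ifelse(!decidable, "reject:decidability", "predict")))
  res <- tibble(prob = prob, in_validity = valid,
                reliability_score = rel$reliability_score,
                similarity_group = rel$similarity_group,
                decidable = decidable, verdict = verdict)
  class(res) <- c("ad_report", class(res))
  res
}
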