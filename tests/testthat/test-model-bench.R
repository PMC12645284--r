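# Metrics, stratified folding, nested CV and configuration comparison

test_that("metrics match closed forms and a brute-force AUC oracle", {
  perfect <- metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$roc_auc, 1)
  expect_equal(perfect$brier, 0)

  half <- metrics(c(1, 0, 1, 0), rep(0.5, 4))
  expect_equal(half$brier, 0.25)

  ex <- metrics(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))
  expect_equal(ex$roc_auc, 0.75)  # 3 of 4 positive/negative pairs ordered

  set.seed(9)
  for (i in 1:10) {
    y <- rbinom(30, 1, 0.5)
    p <- round(runif(30), 2)  # include ties
    if (length(unique(y)) < 2) next
    expect_equal(metrics(y, p)$roc_auc, brute_auc(y, p))
  }
  expect_true(is.na(metrics(rep(1, 5), runif(5))$roc_auc))
})

test_that("stratified folds balance classes within one sample", {
  set.seed(3)
  for (i in 1:10) {
    y <- rbinom(40, 1, 0.4)
    if (min(table(y)) < 5) next
    f <- make_stratified_folds(y, 5)
    counts <- table(f, y)
    expect_true(all(apply(counts, 2, function(ct) diff(range(ct)) <= 1)))
  }
  expect_error(make_stratified_folds(c(1, rep(0, 20)), 5),
               class = "polybiodeg_stratification_error")
})

test_that("nested CV recovers an easily separable planted rule", {
  # aromatic diacid is the single discriminating feature
  rule <- function(diol, diacid) !any(cached_mol(diacid)$aromatic)
  lib <- generate_library(synth_config(120, rule = rule, seed = 11))
  cv <- nested_cv(lib, "rf", "fingerprint", grid = synth_grid(), seed = 1)
  expect_gte(mean(cv$folds$accuracy), 0.95)
  # every sample predicted exactly once across outer folds
  expect_setequal(cv$predictions$idx, seq_len(nrow(lib)))
  expect_true(all(cv$folds$accuracy >= 0 & cv$folds$accuracy <= 1))
})

test_that("label permutation drives ROC-AUC to chance", {
  lib <- fixture_synth_lib()[1:120, ]
  aucs <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    perm <- lib
    perm$label <- sample(perm$label)
    cv <- nested_cv(perm, "rf", "fingerprint",
                    grid = hyper_grid(fingerprint = list(n_bits = 2048, max_path = 6),
                                      rf = list(n_trees = 100, max_depth = 4, mtry = 5)),
                    seed = s)
    mean(cv$folds$roc_auc)
  }, numeric(1))
  expect_gte(mean(aucs), 0.35)
  expect_lte(mean(aucs), 0.65)
})

test_that("the neural network benchmarks run and are seed-deterministic", {
  lib <- fixture_synth_lib()[1:100, ]
  g <- hyper_grid(fingerprint = list(n_bits = 2048, max_path = 6),
                  nn = list(hidden = list(c(8, 0), c(8, 4)), max_iter = 500))
  cv1 <- nested_cv(lib, "nn", "fingerprint", grid = g, seed = 4)
  cv2 <- nested_cv(lib, "nn", "fingerprint", grid = g, seed = 4)
  expect_identical(cv1$predictions$prob, cv2$predictions$prob)
  expect_gte(mean(cv1$folds$accuracy), 0.8)
})

test_that("Friedman statistic matches an independent rank computation", {
  set.seed(7)
  scores <- matrix(round(runif(20, 0.4, 0.9), 2), 5, 4,
                   dimnames = list(NULL, paste0("m", 1:4)))
  rep <- compare_configs(scores)
  # brute-force Friedman with tie correction, as in the classical definition
  r <- t(apply(scores, 1, rank))
  b <- nrow(r); k <- ncol(r)
  A1 <- sum(r^2); C1 <- b * k * (k + 1)^2 / 4
  T1 <- (k - 1) * sum((colSums(r) - b * (k + 1) / 2)^2) / (A1 - C1)
  expect_equal(rep$friedman_statistic, T1, tolerance = 1e-10)
  expect_equal(rep$friedman_p, stats::pchisq(T1, k - 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # Conover statistics agree with the rank-sum formula
  Rj <- colSums(r)
  denom <- sqrt(2 * (b * A1 - sum(Rj^2)) / ((b - 1) * (k - 1)))
  t12 <- abs(Rj[1] - Rj[2]) / denom
  got <- rep$pairwise[rep$pairwise$config1 == "m1" & rep$pairwise$config2 == "m2", ]
  expect_equal(got$statistic, unname(t12), tolerance = 1e-10)
  expect_equal(got$p_value, 2 * pt(-t12, (b - 1) * (k - 1)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("comparison edge cases: ties, Holm monotonicity, pairing errors", {
  tied <- matrix(rep(c(0.7, 0.8, 0.6, 0.9, 0.5), 4), 5, 4)
  rep <- compare_configs(tied)
  expect_equal(rep$friedman_statistic, 0)
  expect_equal(rep$friedman_p, 1)
  expect_true(all(rep$pairwise$p_adjusted == 1))

  set.seed(8)
  scores <- matrix(runif(25), 5, 5)
  rep2 <- compare_configs(scores)
  ord <- order(rep2$pairwise$p_value)
  expect_true(all(diff(rep2$pairwise$p_adjusted[ord]) >= -1e-12))
  expect_true(all(rep2$pairwise$p_adjusted >= rep2$pairwise$p_value))
  expect_true(all(rep2$pairwise$p_value >= 0 & rep2$pairwise$p_adjusted <= 1))

  r1 <- fixture_synth_cv()
  r_bad <- r1; r_bad$folds <- r1$folds[1:4, ]
  expect_error(compare_configs(list(a = r1, b = r1, c = r_bad)),
               class = "polybiodeg_pairing_error")
  expect_error(compare_configs(list(a = r1, b = r1)),
               class = "polybiodeg_contract_error")
})

test_that("tidy and glance summarise cross-validation results", {
  cv <- fixture_synth_cv()
  td <- tidy(cv)
  expect_true(all(c("fold", "accuracy", "n_bits", "max_path") %in% names(td)))
  g <- glance(cv)
  expect_equal(g$n_folds, 5)
  expect_equal(g$accuracy, mean(cv$folds$accuracy))
  expect_true(g$accuracy_sd >= 0)
})
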