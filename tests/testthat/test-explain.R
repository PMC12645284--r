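# Shapley attribution: exactness, atom decomposition, reporting, interactions

# brute-force tree-path-dependent Shapley oracle --------------------------

expvalue_oracle <- function(tr, x, S, node = 1) {
  if (tr$feature[node] < 0) return(tr$value[node])
  f <- tr$feature[node] + 1
  l <- tr$left[node] + 1; r <- tr$right[node] + 1
  if ((f - 1) %in% S) {
    if (x[f] <= tr$threshold[node]) expvalue_oracle(tr, x, S, l)
    else expvalue_oracle(tr, x, S, r)
  } else {
    (tr$cover[l] * expvalue_oracle(tr, x, S, l) +
       tr$cover[r] * expvalue_oracle(tr, x, S, r)) / tr$cover[node]
  }
}

brute_tree_shap <- function(tr, x, p) {
  phi <- numeric(p)
  for (i in 0:(p - 1)) {
    others <- setdiff(0:(p - 1), i)
    for (ssize in 0:length(others)) {
      combos <- if (ssize == 0) list(integer(0)) else
        utils::combn(others, ssize, simplify = FALSE)
      for (S in combos) {
        w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
        phi[i + 1] <- phi[i + 1] +
          w * (expvalue_oracle(tr, x, c(S, i)) - expvalue_oracle(tr, x, S))
      }
    }
  }
  phi
}

test_that("tree Shapley values match the exhaustive coalition oracle", {
  set.seed(5)
  n <- 60; p <- 5
  X <- matrix(rbinom(n * p, 1, 0.5), n, p)
  colnames(X) <- paste0("f", 1:p)
  y <- as.integer(xor(X[, 1] == 1, X[, 3] == 1) | X[, 5] == 1)
  m <- fit_rf(X, y, n_trees = 10, max_depth = 3, mtry = 3, seed = 11)
  fa <- polybiodeg:::rf_forest_arrays(m)
  # manual traversal reproduces ranger probabilities (split semantics)
  manual <- rowMeans(vapply(fa, function(tr) {
    tree_predict_cpp(tr$left, tr$right, tr$feature, tr$threshold, tr$value, X * 1.0)
  }, numeric(n)))
  expect_equal(manual, predict_prob(m, X), tolerance = 1e-12)
  # single trees against the oracle, several samples
  for (t in 1:3) {
    ph <- forest_shap_cpp(fa[t], X[1:4, , drop = FALSE] * 1.0, p)$phi
    for (i in 1:4) {
      expect_equal(ph[i, ], brute_tree_shap(fa[[t]], X[i, ], p), tolerance = 1e-10)
    }
  }
})

test_that("a single-leaf tree attributes nothing", {
  leaf <- list(left = 0L, right = 0L, feature = -1L, threshold = 0,
               value = 0.37, cover = 10)
  res <- forest_shap_cpp(list(leaf), matrix(0, 3, 2), 2)
  expect_equal(res$phi, matrix(0, 3, 2))
  expect_equal(res$base, 0.37)
})

test_that("local accuracy holds on the fitted study model", {
  fm <- fixture_final_model()
  sh <- shap_values(fm)
  err <- max(abs(rowSums(sh$values) + sh$base_value - sh$prob))
  expect_lt(err, 1e-6)
})

test_that("atom decomposition conserves bit attributions and splits equally", {
  fm <- fixture_final_model()
  sh <- shap_values(fm)
  for (i in c(1, 17, 48)) {
    ab <- atoms_from_bits(sh, sample = i)
    expect_equal(sum(ab$atom_scores$score), ab$present_total, tolerance = 1e-9)
    natoms <- mol_n_atoms(mol_parse(fm$data$trimer_smiles[i]))
    expect_true(all(ab$atom_scores$atom >= 1 & ab$atom_scores$atom <= natoms))
  }
  # equal-split rule on a hand-built attribution: one bit, atoms {2, 3}
  attr <- structure(list(
    values = matrix(0.4, 1, 1, dimnames = list(NULL, "b7")),
    base_value = 0.5, feature_names = "b7", prob = 0.9, X = matrix(1, 1, 1),
    final_model = NULL), class = "shap_attribution")
  trace <- list(tibble::tibble(bit = 7L, path = "C-O", atoms = list(c(2L, 3L))))
  ab <- atoms_from_bits(attr, bit_trace = trace, sample = 1)
  expect_equal(ab$atom_scores$score, c(0.2, 0.2))
  # a set bit without trace is an integrity error
  bad_trace <- list(tibble::tibble(bit = integer(0), path = character(0),
                                   atoms = list()))
  expect_error(atoms_from_bits(attr, bit_trace = bad_trace, sample = 1),
               class = "polybiodeg_integrity_error")
})

test_that("feature report: shares normalise, collisions counted", {
  fm <- fixture_final_model()
  sh <- shap_values(fm)
  rep <- feature_report(sh)
  expect_equal(sum(rep$share), 1, tolerance = 1e-9)
  expect_true(all(diff(rep$mean_abs_shap) <= 1e-12))
  g <- glance(rep)
  expect_equal(g$top_share, rep$share[1])
  # hand-built analogue of one bit carrying three distinct moieties
  attr3 <- structure(list(
    values = matrix(c(0.2, 0.1), 1, 2, dimnames = list(NULL, c("b1", "b2"))),
    base_value = 0.5, feature_names = c("b1", "b2"), prob = 0.8,
    X = matrix(1, 1, 2), final_model = NULL), class = "shap_attribution")
  tr3 <- list(tibble::tibble(bit = c(1L, 1L, 1L, 2L),
                             path = c("C-O", "C=O", "C-N", "C-C"),
                             atoms = list(1:2, 2:3, 3:4, 4:5)))
  rep3 <- feature_report(attr3, bit_trace = tr3)
  expect_equal(rep3$n_fragments[rep3$feature == "b1"], 3)
  # real fingerprints do collide at 2048 bits
  fp <- fingerprint(fixture_trimers(), fp_config(2048, 6))
  frag <- dplyr::bind_rows(fp$bit_trace)
  coll <- tapply(frag$path, frag$bit, function(p) length(unique(p)))
  expect_gte(max(coll), 2)
})

test_that("single-feature models give that feature full share", {
  set.seed(2)
  X <- matrix(rbinom(100, 1, 0.5), 100, 1, dimnames = list(NULL, "only"))
  y <- X[, 1]
  m <- fit_rf(X, y, n_trees = 20, max_depth = 2, mtry = 1, seed = 3)
  rep <- feature_report(shap_values(m))
  expect_equal(rep$share[1], 1)
  expect_equal(rep$feature[1], "only")
})

test_that("interaction scan separates additive from XOR structure", {
  set.seed(4)
  n <- 300
  X <- matrix(rbinom(n * 2, 1, 0.5), n, 2, dimnames = list(NULL, c("a", "b")))
  # additive: stumps on disjoint features -> off-diagonal ~ 0
  y_add <- as.integer(X[, 1] == 1)
  m_add <- fit_rf(X, y_add, n_trees = 30, max_depth = 1, mtry = 1, seed = 5)
  sc_add <- interaction_scan(m_add, samples = 1:20)
  expect_lt(sc_add$max_off_diagonal, 0.02)
  # XOR: all signal in the interaction
  y_xor <- as.integer(xor(X[, 1] == 1, X[, 2] == 1))
  m_xor <- fit_rf(X, y_xor, n_trees = 50, max_depth = 2, mtry = 2, seed = 6)
  sc_xor <- interaction_scan(m_xor, samples = 1:20)
  expect_gt(sc_xor$max_off_diagonal, 0.05)
  expect_gt(sc_xor$max_off_diagonal, 3 * sc_add$max_off_diagonal)
  # symmetry and the sum identity
  fa <- polybiodeg:::rf_forest_arrays(m_xor)
  I <- forest_shap_interactions_cpp(fa, X[1, ] * 1.0, 2)
  expect_equal(I, t(I))
  expect_equal(sum(I) + attr(I, "base"), predict_prob(m_xor, X[1, , drop = FALSE]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

# mean Shapley score landing on the aromatic atoms of each molecule that
# has any, via the bit -> atom decomposition
aromatic_atom_mean <- function(model, fp) {
  sh <- shap_values(model)
  scores <- c()
  for (i in seq_len(nrow(sh$values))) {
    g <- mol_parse(fp$smiles[i])
    arom <- which(g$aromatic)
    if (length(arom) == 0) next
    ab <- atoms_from_bits(sh, bit_trace = fp$bit_trace, sample = i)
    scores <- c(scores, ab$atom_scores$score[ab$atom_scores$atom %in% arom])
  }
  mean(scores)
}

test_that("planted aromatic fragments receive negative atom attributions", {
  lib <- fixture_synth_lib()
  fp <- fingerprint(lib, fp_config(2048, 6))
  keep <- polybiodeg:::matrixStats_colVars(fp$matrix) > 0
  X <- fp$matrix[, keep, drop = FALSE]
  # sign recovery across refit seeds
  means <- vapply(1:5, function(s) {
    m <- fit_rf(X, as.integer(lib$label), n_trees = 500, max_depth = 6,
                mtry = 10, seed = s)
    aromatic_atom_mean(m, fp)
  }, numeric(1))
  expect_true(all(means < 0))
})
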