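# Synthetic libraries, traces and domain-shifted pairs

test_that("library generation is seed-deterministic and noise-calibrated", {
  lib1 <- generate_library(synth_config(100, seed = 1))
  lib2 <- generate_library(synth_config(100, seed = 1))
  expect_identical(lib1, lib2)
  expect_identical(lib1$label, lib1$true_label)  # noise = 0
  big <- generate_library(synth_config(10000, label_noise = 0.1, seed = 7))
  expect_lt(abs(mean(big$flipped) - 0.1), 0.01)
  expect_identical(big$label, xor(big$true_label, big$flipped))
  # labels are planted on structure: identical pairs share the true label
  key <- paste(lib1$diol_smiles, lib1$diacid_smiles)
  agree <- tapply(lib1$true_label, key, function(v) length(unique(v)) == 1)
  expect_true(all(agree))
  # trimers carry the expected end groups
  g <- mol_parse(lib1$trimer_smiles[1])
  expect_equal(mol_count_cooh(g), 1)
})

test_that("empty libraries are allowed", {
  lib0 <- generate_library(synth_config(0))
  expect_equal(nrow(lib0), 0)
})

test_that("generated traces always round-trip through the labelling rule", {
  labels <- generate_library(synth_config(100, seed = 3))$label
  traces <- generate_traces(labels, assay_config(), seed = 5)
  recovered <- vapply(traces, label_from_trace, logical(1))
  expect_identical(recovered, labels)
  # degraders decay monotonically; non-degraders stay above pH 6
  for (i in seq_along(labels)) {
    ph <- traces[[i]]$ph
    if (labels[i]) expect_true(all(diff(ph) <= 1e-9)) else expect_true(all(ph > 6))
  }
  # larger deterministic round-trip
  many <- generate_traces(rep(c(TRUE, FALSE), 500), seed = 9)
  expect_identical(vapply(many, label_from_trace, logical(1)),
                   rep(c(TRUE, FALSE), 500))
})

test_that("a source-trained model transfers when chemistry is shared", {
  pair <- generate_shifted_pair(domain_shift_config(shared_fraction = 1,
                                                    n_source = 250, n_target = 250,
                                                    seed = 3))
  cfg <- fp_config(2048, 6)
  Xs <- fingerprint(pair$source, cfg)$matrix
  keep <- polybiodeg:::matrixStats_colVars(Xs) > 0
  m <- fit_rf(Xs[, keep], as.integer(pair$source$label), 200, 6, 10, seed = 1)
  Xt <- fingerprint(pair$target, cfg)$matrix[, keep]
  p <- predict_prob(m, Xt)
  expect_gt(metrics(as.integer(pair$target$label), p)$roc_auc, 0.8)
})

test_that("unshared chemistry exits the source validity domain", {
  pair <- generate_shifted_pair(domain_shift_config(shared_fraction = 0,
                                                    n_source = 120, n_target = 80,
                                                    seed = 4))
  cfg <- fp_config(2048, 6)
  Xs <- fingerprint(pair$source, cfg)$matrix
  Xt <- fingerprint(pair$target, cfg)$matrix
  valid <- validity_check(Xt, fit_ad(Xs))
  expect_gt(sum(!valid), 0)
})

test_that("empty source datasets are produced without error", {
  pair <- generate_shifted_pair(domain_shift_config(n_source = 0, n_target = 10,
                                                    seed = 5))
  expect_equal(nrow(pair$source), 0)
  expect_equal(nrow(pair$target), 10)
})
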