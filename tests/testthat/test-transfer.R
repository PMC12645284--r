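# Chained-model and fine-tuning integration of a source model

test_that("an oracle source feature dominates and lifts target accuracy", {
  lib <- fixture_synth_lib()
  ch <- chain(NULL, lib, grid = chain_grid(), seed = 1,
              source_prob = ifelse(lib$label, 1, 0))
  expect_gte(mean(ch$cv$folds$accuracy), 0.95)
  imp <- importance_of_chain_feature(ch)
  expect_equal(imp$rank, 1L)
  expect_true(imp$rank >= 1 && imp$rank <= imp$n_features)
  expect_true("source_prob" %in% imp$report$feature)
})

test_that("a constant source feature receives no attribution", {
  lib <- fixture_synth_lib()[1:100, ]
  ch <- chain(NULL, lib, grid = synth_grid(), seed = 2,
              source_prob = rep(0.5, 100))
  imp <- importance_of_chain_feature(ch)
  sp <- imp$report[imp$report$feature == "source_prob", ]
  expect_equal(sp$mean_abs_shap, 0, tolerance = 1e-12)
})

test_that("the augmented design has exactly one extra column", {
  lib <- fixture_synth_lib()[1:60, ]
  cfg <- fp_config(2048, 6)
  base_cols <- ncol(fingerprint(lib, cfg)$matrix)
  extra <- matrix(runif(60), ncol = 1, dimnames = list(NULL, "source_prob"))
  sets <- polybiodeg:::prepare_feature_sets(
    lib$trimer_smiles, "fingerprint",
    hyper_grid(fingerprint = list(n_bits = 2048, max_path = 6)), extra)
  expect_equal(ncol(sets[["2048 6"]]), base_cols + 1)
  expect_equal(colnames(sets[["2048 6"]])[base_cols + 1], "source_prob")
})

test_that("fine-tuning runs all three phases and preserves weight shapes", {
  pair <- generate_shifted_pair(domain_shift_config(shared_fraction = 1,
                                                    n_source = 120, n_target = 80,
                                                    seed = 3))
  plan <- finetune_plan(hidden = c(8, 4), pretrain_max_iter = 300,
                        retrain_max_iter = 200)
  ft <- finetune(pair$source, pair$target, plan, seed = 1)
  expect_equal(nrow(ft$folds), 5)
  expect_gte(mean(ft$folds$accuracy), 0.7)
  base <- attr(ft, "pretrained")
  # same architecture across phases: retrain/full-step keep dimensions
  Xt <- fingerprint(pair$target, plan$fp)$matrix
  m2 <- polybiodeg:::mlp_retrain_output(base, Xt, as.integer(pair$target$label), 50)
  m3 <- polybiodeg:::mlp_full_steps(m2, Xt, as.integer(pair$target$label), 1e-4, 1)
  expect_identical(m3$dims, base$dims)
  expect_equal(length(m3$par), length(base$par))
  # only the output layer moved in phase 2
  w_base <- polybiodeg:::mlp_weights(base)
  w_m2 <- polybiodeg:::mlp_weights(m2)
  expect_identical(w_base$Ws, w_m2$Ws)
  expect_false(isTRUE(all.equal(w_base$wout, w_m2$wout)))
})

test_that("a frozen plan reduces to applying the source model", {
  pair <- generate_shifted_pair(domain_shift_config(shared_fraction = 1,
                                                    n_source = 100, n_target = 60,
                                                    seed = 6))
  plan <- finetune_plan(hidden = c(8, 0), pretrain_max_iter = 300,
                        retrain_max_iter = 0, final_epochs = 0)
  ft <- finetune(pair$source, pair$target, plan, seed = 2)
  base <- attr(ft, "pretrained")
  Xt <- fingerprint(pair$target, plan$fp)$matrix
  direct <- predict_prob(base, Xt)
  expect_equal(ft$predictions$prob, direct[ft$predictions$idx], tolerance = 1e-12)
})

test_that("no-shift fine-tuning does not hurt relative to scratch training", {
  pair <- generate_shifted_pair(domain_shift_config(shared_fraction = 1,
                                                    n_source = 150, n_target = 100,
                                                    seed = 8))
  plan <- finetune_plan(hidden = c(8, 0), pretrain_max_iter = 400,
                        retrain_max_iter = 300)
  accs_ft <- accs_scratch <- numeric(5)
  for (s in 1:5) {
    ft <- finetune(pair$source, pair$target, plan, seed = s)
    accs_ft[s] <- mean(ft$folds$accuracy)
    cv <- nested_cv(pair$target, "nn", "fingerprint",
                    grid = hyper_grid(fingerprint = list(n_bits = 2048, max_path = 6),
                                      nn = list(hidden = list(c(8, 0)),
                                                max_iter = 400)),
                    seed = s)
    accs_scratch[s] <- mean(cv$folds$accuracy)
  }
  expect_gte(mean(accs_ft), mean(accs_scratch) - sd(accs_scratch))
})
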