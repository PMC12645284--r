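# Validity, reliability and decidability gating

test_that("tanimoto matches hand counts and is symmetric", {
  expect_equal(tanimoto(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(tanimoto(c(1, 1, 0), c(1, 0, 1)), 1 / 3)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 1)  # empty-set convention
  set.seed(2)
  for (i in 1:20) {
    a <- rbinom(30, 1, 0.3); b <- rbinom(30, 1, 0.3)
    expect_equal(tanimoto(a, b), tanimoto(b, a))
    expect_equal(tanimoto_matrix(rbind(a), rbind(b))[1, 1], tanimoto(a, b))
  }
})

test_that("validity matches a brute-force set-inclusion oracle", {
  set.seed(5)
  train <- matrix(rbinom(20 * 30, 1, 0.25), 20, 30)
  train[, 30] <- 0  # guarantee a never-seen feature
  ad <- fit_ad(train)
  # every training sample is inside its own domain
  expect_true(all(validity_check(train, ad)))
  probes <- matrix(rbinom(100 * 30, 1, 0.25), 100, 30)
  got <- validity_check(probes, ad)
  seen <- which(colSums(train) > 0)
  core <- which(colSums(train) == nrow(train))
  oracle <- vapply(seq_len(nrow(probes)), function(i) {
    bits <- which(probes[i, ] == 1)
    all(bits %in% seen) && all(core %in% bits)
  }, logical(1))
  expect_identical(got, oracle)
  # one never-seen bit is enough for rejection
  x <- train[1, ]
  x[which(colSums(train) == 0)[1]] <- 1
  expect_false(validity_check(x, ad))
})

test_that("validity is monotone under training-set growth", {
  set.seed(6)
  train <- matrix(rbinom(15 * 25, 1, 0.3), 15, 25)
  probes <- matrix(rbinom(60 * 25, 1, 0.3), 60, 25)
  before <- validity_check(probes, fit_ad(train))
  for (i in 1:5) {
    train <- rbind(train, rbinom(25, 1, 0.3))
    after <- validity_check(probes, fit_ad(train))
    expect_true(all(after[before]))  # no probe leaves the domain
    before <- after
  }
})

test_that("reliability scores agree with exhaustive search and ignore order", {
  m <- matrix(rbinom(8 * 40, 1, 0.4), 8, 40)
  cfg <- ad_config(k_neighbors = 1)
  sc <- reliability_scores(m[1:3, ], cfg, mode = "loo")
  for (i in 1:3) {
    sims <- vapply(setdiff(1:3, i), function(j) tanimoto(m[i, ], m[j, ]), numeric(1))
    expect_equal(sc$reliability_score[i], max(sims))
  }
  # identical molecules: all scores 1, all high group
  dup <- m[rep(1, 7), ]
  sc2 <- reliability_scores(dup, ad_config(), mode = "loo")
  expect_true(all(sc2$reliability_score == 1))
  expect_true(all(sc2$similarity_group == "high"))
  # order invariance
  perm <- sample(nrow(m))
  s_a <- reliability_scores(m, ad_config(k_neighbors = 3), mode = "loo")
  s_b <- reliability_scores(m[perm, ], ad_config(k_neighbors = 3), mode = "loo")
  expect_equal(s_b$reliability_score, s_a$reliability_score[perm])
  expect_error(reliability_scores(m[1:4, ], ad_config(k_neighbors = 5), mode = "loo"),
               class = "polybiodeg_contract_error")
})

test_that("calibration bins respect the minimum size and track frequencies", {
  set.seed(11)
  p <- runif(1000)
  y <- rbinom(1000, 1, p)
  grp <- factor(rep("high", 1000), levels = c("low", "mid", "high"))
  cc <- calibration_curves(p, y, grp, ad_config(min_bin_size = 100))
  expect_true(all(cc$n >= 100))
  expect_lte(max(abs(cc$obs_freq - cc$mean_prob)), 0.15)
  # all-positive group with probability 1 collapses to the (1, 1) point
  one <- calibration_curves(rep(1, 6), rep(1, 6),
                            factor(rep("high", 6), levels = c("low", "mid", "high")),
                            ad_config(min_bin_size = 6))
  expect_equal(nrow(one), 1)
  expect_equal(one$mean_prob, 1)
  expect_equal(one$obs_freq, 1)
  # undersized group is skipped with a warning
  expect_warning(
    small <- calibration_curves(runif(3), rbinom(3, 1, 0.5),
                                factor(rep("mid", 3), levels = c("low", "mid", "high")),
                                ad_config(min_bin_size = 4)),
    "skipped"
  )
  expect_equal(nrow(small), 0)
})

test_that("gates fire in order: validity, reliability, decidability", {
  train <- matrix(rep(c(1, 1, 0, 0, 1), 10), 10, 5, byrow = TRUE)
  ad <- fit_ad(train, ad_config(decidability_delta = 0.1))
  # novel bit: rejected regardless of probability
  novel <- c(1, 1, 1, 0, 1)
  expect_equal(gate(0.99, novel, ad)$verdict, "reject:validity")
  # in-domain, high similarity, but indecisive probability
  ok <- train[1, ]
  expect_equal(gate(0.52, ok, ad)$verdict, "reject:decidability")
  expect_equal(gate(0.95, ok, ad)$verdict, "predict")
  rep <- gate(c(0.99, 0.52, 0.95), rbind(novel, ok, ok), ad)
  expect_true(all(rep$verdict[rep$verdict == "predict"] == "predict"))
  expect_true(all(rep$in_validity[rep$verdict == "predict"]))
})
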