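# Shared fixtures, memoised across test files (test_dir runs in one process).
# Everything is generated in code; nothing is read from outside the package.

the_test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(the_test_cache[[key]])) the_test_cache[[key]] <- force(expr)
  the_test_cache[[key]]
}

fixture_table1 <- function() memo("table1", load_table1())

fixture_trimers <- function() {
  memo("trimers", build_dataset_trimers(fixture_table1()))
}

# reduced grid used at synthetic scale: one fingerprint setting able to see
# both carbonyls of the longest biodegradable diacid, and a small RF grid
synth_grid <- function() {
  hyper_grid(fingerprint = list(n_bits = 2048, max_path = 6),
             rf = list(n_trees = 200, max_depth = c(4, 6), mtry = c(5, 10)))
}

# chained-model study conditions: a single deep, many-tree configuration so
# that one appended feature is not drowned by noise-tree variance
chain_grid <- function() {
  hyper_grid(fingerprint = list(n_bits = 2048, max_path = 6),
             rf = list(n_trees = 500, max_depth = 6, mtry = 10))
}

fixture_synth_lib <- function() {
  memo("synth_lib", generate_library(synth_config(200, seed = 7)))
}

fixture_synth_cv <- function() {
  memo("synth_cv",
       nested_cv(fixture_synth_lib(), "rf", "fingerprint", grid = synth_grid(),
                 seed = 1))
}

# the ten-seed study benchmark backing the reproduction checks
fixture_bench_seeds <- function() 1:10

fixture_bench_cvs <- function() {
  memo("bench_cvs", lapply(fixture_bench_seeds(), function(s) {
    nested_cv(fixture_trimers(), "rf", "fingerprint", seed = s)
  }))
}

fixture_final_model <- function() {
  memo("final_model", final_model(fixture_trimers(), "rf", "fingerprint", seed = 1))
}

fixture_synth_final_model <- function() {
  memo("synth_final_model",
       final_model(fixture_synth_lib(), "rf", "fingerprint", grid = synth_grid(),
                   seed = 1))
}

# brute-force helpers -------------------------------------------------------

# all connected edge-induced subgraphs with 1..k edges, as sorted edge-index
# sets (oracle for the fingerprint enumeration)
brute_connected_subgraphs <- function(bonds, k) {
  m <- nrow(bonds)
  out <- list()
  for (size in seq_len(min(k, m))) {
    for (comb in utils::combn(m, size, simplify = FALSE)) {
      atoms <- unique(c(bonds[comb, 1], bonds[comb, 2]))
      # connectivity over chosen edges
      seen <- atoms[1]
      repeat {
        grow <- unique(c(
          bonds[comb, 2][bonds[comb, 1] %in% seen],
          bonds[comb, 1][bonds[comb, 2] %in% seen]
        ))
        new <- setdiff(grow, seen)
        if (length(new) == 0) break
        seen <- c(seen, new)
      }
      if (setequal(seen, atoms)) out[[length(out) + 1]] <- sort(comb)
    }
  }
  out
}

# rank-based AUC oracle: fraction of positive/negative pairs ordered
# correctly, ties counting one half
brute_auc <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
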