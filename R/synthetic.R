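# Synthetic polymer libraries with planted structure -> label rules,
# synthetic pH-decay traces consistent with those labels, and domain-shifted
# source/target dataset pairs. Everything downstream of the chemistry module
# can be exercised against known ground truth without any external data.

default_diol_pool <- function() {
  tibble(
    name = c("1,4-Butanediol", "1,10-Decanediol", "Diethylene glycol",
             "Triethylene glycol", "Tetraethylene glycol", "Glycerol",
             "Diglycerol", "Sorbitol"),
    smiles = c("OCCCCO", "OCCCCCCCCCCO", "OCCOCCO", "OCCOCCOCCO",
               "OCCOCCOCCOCCO", "OCC(O)CO", "OCC(O)COCC(O)CO",
               "OCC(O)C(O)C(O)C(O)CO"),
    role = c("diol", "diol", "diol", "diol", "diol", "polyol", "polyol", "polyol")
  )
}

default_diacid_pool <- function() {
  tibble(
    name = c("Succinic acid", "Glutaric acid", "Adipic acid", "Sebacic acid",
             "Terephthalic acid", "Furan-2,5-dicarboxylic acid"),
    smiles = c("OC(=O)CCC(=O)O", "OC(=O)CCCC(=O)O", "OC(=O)CCCCC(=O)O",
               "OC(=O)CCCCCCCCC(=O)O", "OC(=O)c1ccc(C(=O)O)cc1",
               "OC(=O)c1ccc(o1)C(=O)O"),
    role = "diacid"
  )
}

# held-out monomers used as "novel chemistry" for domain-shifted targets
novel_diol_pool <- function() {
  tibble(
    name = c("2,2-Dimethyl-1,3-propanediol", "2-Butene-1,4-diol",
             "1,2-Propanediol", "1,4-Cyclohexanedimethanol"),
    smiles = c("OCC(C)(C)CO", "OCC=CCO", "CC(O)CO", "OCC1CCC(CO)CC1"),
    role = "diol"
  )
}

novel_diacid_pool <- function() {
  tibble(
    name = c("Azelaic acid", "Suberic acid", "Isophthalic acid",
             "Cyclobutane-1,1-dicarboxylic acid"),
    smiles = c("OC(=O)CCCCCCCC(=O)O", "OC(=O)CCCCCCC(=O)O",
               "OC(=O)c1cccc(C(=O)O)c1", "OC(=O)C1(C(=O)O)CCC1"),
    role = "diacid"
  )
}

# structural predicates the planted rule is built from --------------------

monomer_is_aromatic <- function(smiles) any(cached_mol(smiles)$aromatic)

# carbons separating the two carboxyl carbons (graph distance - 1)
diacid_chain_length <- function(smiles) {
  g <- cached_mol(smiles)
  cc <- mol_carboxyl_groups(g)$carbonyl_c
  if (length(cc) < 2) return(NA_integer_)
  # BFS distance
  dist <- rep(NA_integer_, mol_n_atoms(g))
  dist[cc[1]] <- 0L
  frontier <- cc[1]
  while (length(frontier) > 0 && is.na(dist[cc[2]])) {
    nxt <- unique(unlist(lapply(frontier, mol_neighbors, g = g)))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- dist[frontier[1]] + 1L
    frontier <- nxt
  }
  dist[cc[2]] - 1L
}

# an oxygen beyond the two condensing hydroxyls: ether O or a third OH
diol_has_extra_oxygen <- function(smiles) {
  g <- cached_mol(smiles)
  n_oh <- length(mol_hydroxyl_oxygens(g))
  n_ether <- sum(vapply(seq_along(g$elem), function(i) {
    g$elem[i] == "O" && !g$aromatic[i] && mol_degree(g, i) == 2
  }, logical(1)))
  n_oh > 2 || n_ether > 0
}

#' The default planted structure -> label rule
#'
#' A polymer is labelled biodegradable iff the diacid is aliphatic with at
#' most `max_chain` backbone carbons between its carboxyl groups, and the
#' diol carries an oxygen beyond the two condensing hydroxyls (an ether
#' oxygen or a pendant hydroxyl).
#'
#' @param max_chain maximum aliphatic diacid chain length (default 4).
#' @return a predicate `function(diol_smiles, diacid_smiles) -> logical`.
#' @export
default_rule <- function(max_chain = 4) {
  force(max_chain)
  function(diol_smiles, diacid_smiles) {
    !monomer_is_aromatic(diacid_smiles) &&
      diacid_chain_length(diacid_smiles) <= max_chain &&
      diol_has_extra_oxygen(diol_smiles)
  }
}

#' Synthetic-library configuration
#'
#' @param n_polymers number of polymers to draw.
#' @param diols,diacids monomer pools (tibbles with `name`, `smiles`, `role`).
#' @param rule structure -> label predicate (default [default_rule()]).
#' @param label_noise per-label flip probability in `[0, 0.5]`.
#' @param seed RNG seed.
#' @return a `synth_config` object.
#' @export
synth_config <- function(n_polymers = 100, diols = default_diol_pool(),
                         diacids = default_diacid_pool(), rule = default_rule(),
                         label_noise = 0, seed = 1) {
  stopifnot(label_noise >= 0, label_noise <= 0.5,
            nrow(diols) > 0, nrow(diacids) > 0, n_polymers >= 0)
  structure(list(n_polymers = n_polymers, diols = diols, diacids = diacids,
                 rule = rule, label_noise = label_noise, seed = seed),
            class = "synth_config")
}

#' Generate a synthetic polymer library with planted labels
#'
#' Diol/diacid pairs are drawn uniformly with replacement; the true label is
#' the planted rule applied to the pair, and the observed label is the true
#' label XOR independent noise flips. Trimers are built with the same
#' chemistry as the study dataset.
#'
#' @param cfg a [synth_config()].
#' @return a tibble: `id`, `monomer1`, `monomer2`, `diol_smiles`,
#'   `diacid_smiles`, `trimer_smiles`, `true_label`, `label`, `flipped`.
#' @export
generate_library <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_polymers
  di <- sample.int(nrow(cfg$diols), n, replace = TRUE)
  da <- sample.int(nrow(cfg$diacids), n, replace = TRUE)
  flips <- rbinom(n, 1, cfg$label_noise) == 1
  if (n == 0) {
    return(tibble(id = integer(0), monomer1 = character(0), monomer2 = character(0),
                  diol_smiles = character(0), diacid_smiles = character(0),
                  trimer_smiles = character(0), true_label = logical(0),
                  label = logical(0), flipped = logical(0)))
  }
  recs <- tibble(
    id = seq_len(n),
    monomer1 = cfg$diols$name[di], monomer2 = cfg$diacids$name[da],
    diol_smiles = cfg$diols$smiles[di], diacid_smiles = cfg$diacids$smiles[da]
  )
  true_label <- vapply(seq_len(n), function(i) {
    v <- cfg$rule(recs$diol_smiles[i], recs$diacid_smiles[i])
    if (is.na(v)) abort("planted rule not evaluable on a generated structure",
                        class = "polybiodeg_generation_error")
    v
  }, logical(1))
  # one trimer build per distinct monomer pair
  pair_key <- paste(recs$diol_smiles, recs$diacid_smiles)
  uniq <- !duplicated(pair_key)
  tri_map <- new.env(parent = emptyenv())
  for (i in which(uniq)) {
    diol <- monomer_spec(recs$monomer1[i], recs$diol_smiles[i],
                         cfg$diols$role[di[i]])
    acid <- monomer_spec(recs$monomer2[i], recs$diacid_smiles[i], "diacid")
    tri_map[[pair_key[i]]] <- build_nmer(condense(diol, acid), 3)$smiles
  }
  recs %>%
    mutate(
      trimer_smiles = vapply(pair_key, function(k) tri_map[[k]], character(1),
                             USE.NAMES = FALSE),
      true_label = true_label,
      label = xor(true_label, flips),
      flipped = flips
    )
}

#' Generate synthetic pH traces consistent with a set of labels
#'
#' Degraders follow a monotone sigmoidal pH decay from ~7 to a plateau below
#' the assay cutoff reached before the endpoint (rate and plateau jittered
#' per sample); non-degraders fluctuate mildly above pH 6. By construction
#' [label_from_trace()] recovers the input label for every trace.
#'
#' @param labels logical vector.
#' @param cfg an [assay_config()].
#' @param seed RNG seed.
#' @return list of trace tibbles (`times` in minutes, `ph`).
#' @export
generate_traces <- function(labels, cfg = assay_config(), seed = 1) {
  set.seed(seed)
  t_end_min <- cfg$t_end * 60
  times <- seq(0, t_end_min, by = cfg$sampling_interval)
  if (max(times) < t_end_min) times <- c(times, t_end_min)
  purrr::map(labels, function(lab) {
    if (lab) {
      plateau <- runif(1, 4.2, cfg$ph_cutoff - 0.2)
      midpoint <- runif(1, 0.15, 0.5) * t_end_min
      rate <- t_end_min / runif(1, 12, 25)
      ph <- plateau + (7 - plateau) / (1 + exp((times - midpoint) / rate))
      # monotone by construction; force the endpoint below the cutoff
      ph[length(ph)] <- min(ph[length(ph)], cfg$ph_cutoff - 0.1)
      ph <- rev(cummax(rev(ph)))
    } else {
      ph <- 7 + rnorm(length(times), sd = 0.05)
      ph <- pmax(ph, 6.1)
    }
    tibble(times = times, ph = ph)
  })
}

#' Domain-shift configuration for source/target dataset pairs
#'
#' @param shared_fraction fraction of the target monomer pool shared with the
#'   source pool (1 = identical chemistry, 0 = fully novel monomers).
#' @param source_rule,target_rule planted label predicates.
#' @param n_source,n_target library sizes.
#' @param label_noise shared flip probability.
#' @param seed RNG seed.
#' @return a `domain_shift_config` object.
#' @export
domain_shift_config <- function(shared_fraction = 1, source_rule = default_rule(),
                                target_rule = default_rule(), n_source = 200,
                                n_target = 100, label_noise = 0, seed = 1) {
  stopifnot(shared_fraction >= 0, shared_fraction <= 1)
  structure(list(shared_fraction = shared_fraction, source_rule = source_rule,
                 target_rule = target_rule, n_source = n_source,
                 n_target = n_target, label_noise = label_noise, seed = seed),
            class = "domain_shift_config")
}

#' Generate a domain-shifted source/target dataset pair
#'
#' The source library draws from the default monomer pools. The target pool
#' keeps a `shared_fraction` of those monomers and replaces the rest with
#' held-out novel monomers, so feature supports diverge as the fraction
#' shrinks (novel fingerprint bits appear in the target).
#'
#' @param cfg a [domain_shift_config()].
#' @return list with `source` and `target` library tibbles.
#' @export
generate_shifted_pair <- function(cfg = domain_shift_config()) {
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max, 3)
  base_diols <- default_diol_pool(); base_acids <- default_diacid_pool()
  n_keep_d <- round(cfg$shared_fraction * nrow(base_diols))
  n_keep_a <- round(cfg$shared_fraction * nrow(base_acids))
  keep_d <- sample.int(nrow(base_diols), n_keep_d)
  keep_a <- sample.int(nrow(base_acids), n_keep_a)
  nd <- novel_diol_pool(); na_ <- novel_diacid_pool()
  tgt_diols <- bind_rows(base_diols[keep_d, ],
                         nd[seq_len(min(nrow(nd), nrow(base_diols) - n_keep_d)), ])
  tgt_acids <- bind_rows(base_acids[keep_a, ],
                         na_[seq_len(min(nrow(na_), nrow(base_acids) - n_keep_a)), ])
  if (nrow(tgt_diols) == 0) tgt_diols <- nd
  if (nrow(tgt_acids) == 0) tgt_acids <- na_
  src <- generate_library(synth_config(cfg$n_source, base_diols, base_acids,
                                       cfg$source_rule, cfg$label_noise, seeds[1]))
  tgt <- generate_library(synth_config(cfg$n_target, tgt_diols, tgt_acids,
                                       cfg$target_rule, cfg$label_noise, seeds[2]))
  list(source = src, target = tgt)
}
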