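# Construction of polyester repeat units and trimer SMILES from monomers.
#
# Polycondensation joins a diol (or polyol, through its two highest-ranked
# primary hydroxyls) with a diacid or dimethyl diester, eliminating water or
# methanol per ester bond. Ring-opening polymerisation opens one ring-ester
# bond of a lactone (for cyclic di-esters such as lactide this yields the
# two-unit repeat). Trimers are capped with one alcohol and one carboxylic
# acid end group, mirroring a chain initiated on a hydroxyl and terminated on
# an acyl end.

#' Describe a monomer for polymer construction
#'
#' @param name free-text monomer name.
#' @param smiles SMILES string (canonicalised internally).
#' @param role one of `"diol"`, `"polyol"`, `"diacid"`, `"dimethyl_ester"`,
#'   `"lactone"`.
#' @param reactive_sites optional integer atom indices (into the canonical
#'   SMILES atom order) overriding automatic selection of the condensation
#'   sites: hydroxyl oxygens for (poly)ols, acyl carbons for acids/esters.
#' @return a `monomer_spec` object.
#' @export
monomer_spec <- function(name, smiles, role, reactive_sites = NULL) {
  role <- match.arg(role, c("diol", "polyol", "diacid", "dimethyl_ester", "lactone"))
  g <- mol_parse(smiles)
  spec <- structure(
    list(name = name, smiles = g$smiles, role = role, graph = g,
         reactive_sites = reactive_sites),
    class = "monomer_spec"
  )
  validate_monomer_spec(spec)
  spec
}

validate_monomer_spec <- function(spec) {
  g <- spec$graph
  ok <- switch(spec$role,
    diol = ,
    polyol = length(mol_hydroxyl_oxygens(g)) >= 2,
    diacid = nrow(mol_carboxyl_groups(g)) == 2,
    dimethyl_ester = nrow(mol_methyl_ester_groups(g)) == 2,
    lactone = nrow(mol_ring_esters(g)) >= 1
  )
  if (!ok) {
    abort(paste0("monomer '", spec$name, "' does not satisfy the structural ",
                 "requirements of role '", spec$role, "'"),
          class = "polybiodeg_structure_error")
  }
  invisible(spec)
}

#' @export
print.monomer_spec <- function(x, ...) {
  cat("<monomer_spec> ", x$name, " [", x$role, "] ", x$smiles, "\n", sep = "")
  invisible(x)
}

# hydroxyls ranked primary-first (carbon carrier with <= 2 heavy neighbours),
# then by canonical atom index; the first two are the condensation sites
choose_diol_sites <- function(spec) {
  if (!is.null(spec$reactive_sites)) return(spec$reactive_sites[1:2])
  g <- spec$graph
  oh <- mol_hydroxyl_oxygens(g)
  primary <- vapply(oh, function(o) {
    c_atom <- mol_neighbors(g, o)[1]
    mol_degree(g, c_atom) <= 2 && !g$aromatic[c_atom]
  }, logical(1))
  ranked <- c(oh[primary], oh[!primary])
  ranked[1:2]
}

choose_acyl_sites <- function(spec) {
  if (!is.null(spec$reactive_sites)) return(spec$reactive_sites[1:2])
  g <- spec$graph
  if (spec$role == "diacid") sort(mol_carboxyl_groups(g)$carbonyl_c)[1:2]
  else sort(mol_methyl_ester_groups(g)$carbonyl_c)[1:2]
}

#' Condense a diol with a diacid or dimethyl diester into a repeat unit
#'
#' One ester bond is formed inside the repeat unit (between the diol's
#' second-ranked hydroxyl oxygen and the acyl component's first carbonyl
#' carbon); the remaining hydroxyl oxygen and carbonyl carbon are the
#' alcohol-side and acyl-side attachment points. Methanol is eliminated per
#' bond for dimethyl esters, water for diacids. Pendant hydroxyls of branched
#' polyols are left unreacted (linear-chain treatment).
#'
#' @param diol a `monomer_spec` with role `"diol"` or `"polyol"`.
#' @param acyl a `monomer_spec` with role `"diacid"` or `"dimethyl_ester"`.
#' @return a `repeat_unit` object.
#' @export
condense <- function(diol, acyl) {
  stopifnot(inherits(diol, "monomer_spec"), inherits(acyl, "monomer_spec"))
  if (!diol$role %in% c("diol", "polyol")) {
    abort(paste0("'", diol$name, "' has role '", diol$role,
                 "'; expected diol or polyol"), class = "polybiodeg_contract_error")
  }
  if (!acyl$role %in% c("diacid", "dimethyl_ester")) {
    abort(paste0("'", acyl$name, "' has role '", acyl$role,
                 "'; expected diacid or dimethyl_ester"), class = "polybiodeg_contract_error")
  }
  dg <- diol$graph
  ag <- acyl$graph
  d_sites <- choose_diol_sites(diol)
  a_sites <- choose_acyl_sites(acyl)

  # strip leaving groups from both acyl ends
  if (acyl$role == "dimethyl_ester") {
    grp <- mol_methyl_ester_groups(ag)
    grp <- grp[match(a_sites, grp$carbonyl_c), ]
    drop <- c(grp$ester_o, grp$methyl_c)
    eliminated <- "methanol"
  } else {
    grp <- mol_carboxyl_groups(ag)
    grp <- grp[match(a_sites, grp$carbonyl_c), ]
    drop <- grp$oh_o
    eliminated <- "water"
  }
  keep_map <- integer(mol_n_atoms(ag))
  keep <- setdiff(seq_len(mol_n_atoms(ag)), drop)
  keep_map[keep] <- seq_along(keep)
  ag2 <- mol_delete_atoms(ag, drop)
  a_sites2 <- keep_map[a_sites]

  off <- mol_n_atoms(dg)
  g <- mol_combine(dg, ag2)
  # internal ester bond: diol site 2 -- acyl site 1
  g <- mol_add_bond(g, d_sites[2], a_sites2[1] + off)

  structure(
    list(graph = g,
         head_o = d_sites[1],               # alcohol-side attachment
         tail_c = a_sites2[2] + off,        # acyl-side attachment
         eliminated = eliminated,
         source_monomers = c(diol$name, acyl$name)),
    class = "repeat_unit"
  )
}

#' Ring-open a lactone into a repeat unit
#'
#' Exactly one ring-ester C(=O)-O bond is broken, giving a linear
#' -O-...-C(=O)- repeat with no atoms eliminated. Cyclic di-esters (lactide,
#' glycolide) therefore open into a two-unit repeat.
#'
#' @param lactone a `monomer_spec` with role `"lactone"`.
#' @return a `repeat_unit` object.
#' @export
ring_open <- function(lactone) {
  stopifnot(inherits(lactone, "monomer_spec"))
  if (lactone$role != "lactone") {
    abort(paste0("'", lactone$name, "' has role '", lactone$role, "'; expected lactone"),
          class = "polybiodeg_structure_error")
  }
  g <- lactone$graph
  re <- mol_ring_esters(g)
  if (nrow(re) == 0) {
    abort(paste0("no ring ester found in '", lactone$name, "'"),
          class = "polybiodeg_structure_error")
  }
  g2 <- mol_delete_bond(g, re$carbonyl_c[1], re$ester_o[1])
  structure(
    list(graph = g2, head_o = re$ester_o[1], tail_c = re$carbonyl_c[1],
         eliminated = "none", source_monomers = lactone$name),
    class = "repeat_unit"
  )
}

#' Join two repeat units into one composite (alternating comonomer) repeat
#'
#' An ester bond is formed between the first unit's acyl-side carbon and the
#' second unit's alcohol-side oxygen; the composite inherits the first unit's
#' alcohol-side and the second unit's acyl-side attachment points.
#'
#' @param a,b `repeat_unit` objects.
#' @return a `repeat_unit`.
#' @export
combine_repeats <- function(a, b) {
  stopifnot(inherits(a, "repeat_unit"), inherits(b, "repeat_unit"))
  off <- mol_n_atoms(a$graph)
  g <- mol_combine(a$graph, b$graph)
  g <- mol_add_bond(g, a$tail_c, b$head_o + off)
  structure(
    list(graph = g, head_o = a$head_o, tail_c = b$tail_c + off,
         eliminated = paste(unique(c(a$eliminated, b$eliminated)), collapse = "+"),
         source_monomers = c(a$source_monomers, b$source_monomers)),
    class = "repeat_unit"
  )
}

#' @export
print.repeat_unit <- function(x, ...) {
  cat("<repeat_unit> ", paste(x$source_monomers, collapse = " / "), "\n  ",
      mol_n_atoms(x$graph), " heavy atoms, eliminated: ", x$eliminated, "\n", sep = "")
  invisible(x)
}

#' SMILES of a repeat unit with explicit attachment points
#'
#' Attachment points are written as `[*]` dummy atoms bonded to the
#' alcohol-side oxygen and the acyl-side carbon.
#'
#' @param repeat_unit a `repeat_unit`.
#' @return a SMILES string.
#' @export
repeat_unit_smiles <- function(repeat_unit) {
  g <- repeat_unit$graph
  off <- mol_n_atoms(g)
  g$elem <- c(g$elem, "*", "*")
  g$aromatic <- c(g$aromatic, FALSE, FALSE)
  g <- mol_add_bond(g, repeat_unit$head_o, off + 1L)
  g <- mol_add_bond(g, repeat_unit$tail_c, off + 2L)
  mol_to_smiles(g)
}

#' Build a linear n-mer from a repeat unit
#'
#' `n` copies of the repeat are joined head-to-tail in a fixed orientation;
#' the alcohol-side terminus keeps its hydroxyl (implicit hydrogen) and the
#' acyl-side terminus is capped with a hydroxyl, giving one terminal alcohol
#' and one terminal carboxylic acid.
#'
#' @param repeat_unit a `repeat_unit`.
#' @param n degree of polymerisation (default 3: the trimer representation).
#' @return a `trimer_structure` object with fields `smiles`, `n`,
#'   `heavy_atoms`, `repeat_unit`.
#' @export
build_nmer <- function(repeat_unit, n = 3) {
  stopifnot(inherits(repeat_unit, "repeat_unit"))
  n <- as.integer(n)
  if (is.na(n) || n < 1) abort("n must be a positive integer",
                               class = "polybiodeg_contract_error")
  ru <- repeat_unit
  g <- ru$graph
  head_o <- ru$head_o
  tail_c <- ru$tail_c
  nr <- mol_n_atoms(ru$graph)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      off <- mol_n_atoms(g)
      g <- mol_combine(g, ru$graph)
      g <- mol_add_bond(g, tail_c, off + ru$head_o)
      tail_c <- off + ru$tail_c
    }
  }
  # cap acyl terminus with OH -> terminal COOH
  g$elem <- c(g$elem, "O")
  g$aromatic <- c(g$aromatic, FALSE)
  g <- mol_add_bond(g, tail_c, mol_n_atoms(g))
  smiles <- mol_to_smiles(g)
  structure(
    list(smiles = smiles, n = n, heavy_atoms = mol_n_atoms(g),
         end_groups = c("alcohol", "acid"), repeat_unit = ru),
    class = "trimer_structure"
  )
}

#' @export
print.trimer_structure <- function(x, ...) {
  cat("<trimer_structure> n=", x$n, ", ", x$heavy_atoms, " heavy atoms\n  ",
      x$smiles, "\n", sep = "")
  invisible(x)
}

#' Load the monomer registry
#'
#' The registry is a CSV with columns `name`, `smiles`, `role`. The packaged
#' registry covers every monomer of the study dataset plus the monomers used
#' by the synthetic-library generator.
#'
#' @param path optional path to a registry CSV; defaults to the packaged one.
#' @return a tibble with columns `name`, `smiles`, `role`.
#' @export
load_monomer_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "monomers.csv", package = "polybiodeg")
  }
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

resolve_monomer <- function(name, registry) {
  hit <- which(registry$name == name)
  if (length(hit) != 1) {
    abort(paste0("monomer name not found in registry: '", name, "'"),
          class = "polybiodeg_lookup_error")
  }
  monomer_spec(registry$name[hit], registry$smiles[hit], registry$role[hit])
}

build_record_repeat <- function(m1, m2) {
  if (m1$role == "lactone" && is.null(m2)) {
    ring_open(m1)
  } else if (m1$role == "lactone" && m2$role == "lactone") {
    combine_repeats(ring_open(m1), ring_open(m2))
  } else {
    # orient: diol first, acyl second, whichever order the record lists them
    if (m1$role %in% c("diol", "polyol")) condense(m1, m2) else condense(m2, m1)
  }
}

#' Build trimer structures for a dataset of monomer records
#'
#' @param records tibble with columns `monomer1` and `monomer2` (`NA` or ""
#'   for homopolymer lactones); other columns are carried through.
#' @param registry monomer registry tibble (default: packaged registry).
#' @param n degree of polymerisation (default 3).
#' @return the input tibble with `trimer_smiles`, `repeat_smiles` and
#'   `heavy_atoms` columns appended.
#' @export
build_dataset_trimers <- function(records, registry = load_monomer_registry(), n = 3) {
  records <- as_tibble(records)
  cache <- new.env(parent = emptyenv())
  build_one <- function(m1_name, m2_name) {
    key <- paste(m1_name, m2_name, n, sep = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    m1 <- resolve_monomer(m1_name, registry)
    m2 <- if (is.na(m2_name) || !nzchar(m2_name)) NULL else resolve_monomer(m2_name, registry)
    ru <- build_record_repeat(m1, m2)
    tr <- build_nmer(ru, n = n)
    cache[[key]] <- tr
    tr
  }
  m2 <- if ("monomer2" %in% names(records)) records$monomer2 else rep(NA_character_, nrow(records))
  built <- purrr::map2(records$monomer1, m2, build_one)
  records %>%
    mutate(
      trimer_smiles = vapply(built, function(t) t$smiles, character(1)),
      repeat_smiles = vapply(built, function(t) repeat_unit_smiles(t$repeat_unit), character(1)),
      heavy_atoms = vapply(built, function(t) t$heavy_atoms, integer(1))
    )
}
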