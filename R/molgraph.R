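# Lightweight heavy-atom molecular graph used for polymer construction and
# path enumeration. Parsing and canonicalisation are delegated to OpenBabel
# (via ChemmineR/ChemmineOB); this file only walks and edits the graph.

ob_canonical_smiles <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", source = smiles),
    error = function(e) ""
  )
  out <- sub("\t.*", "", out)
  out <- trimws(strsplit(out, "\n", fixed = TRUE)[[1]][1])
  if (is.na(out) || !nzchar(out)) {
    abort(paste0("could not parse SMILES: '", smiles, "'"), class = "polybiodeg_structure_error")
  }
  out
}

# atom tokens of a SMILES string, in writing order, with aromatic flags.
# Handles the organic subset plus bracket atoms; enough for the chemistry here.
smiles_atom_tokens <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  elems <- character(0)
  arom <- logical(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      sym <- sub("^[0-9]*", "", inner)
      sym <- regmatches(sym, regexpr("^[A-Za-z][a-z]?", sym))
      if (length(sym) == 1 && sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")) {
        elems <- c(elems, paste0(toupper(substr(sym, 1, 1)), substring(sym, 2)))
        arom <- c(arom, TRUE)
      } else {
        elems <- c(elems, sym)
        arom <- c(arom, FALSE)
      }
      i <- j + 1L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      nxt <- if (i < n) chars[i + 1L] else ""
      two <- paste0(ch, nxt)
      if (two %in% c("Cl", "Br")) {
        elems <- c(elems, two)
        arom <- c(arom, FALSE)
        i <- i + 2L
      } else {
        elems <- c(elems, ch)
        arom <- c(arom, FALSE)
        i <- i + 1L
      }
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      elems <- c(elems, toupper(ch))
      arom <- c(arom, TRUE)
      i <- i + 1L
    } else {
      # ring closures, branches, bonds, stereo marks
      i <- i + 1L
    }
  }
  tibble(elem = elems, aromatic = arom)
}

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' The SMILES is canonicalised with OpenBabel first, so identical molecules
#' always yield identical graphs (and identical atom numbering).
#'
#' @param smiles a single SMILES string describing one connected molecule.
#' @return an object of class `molgraph`: a list with `elem` (element symbol
#'   per atom), `aromatic` (logical per atom), `bonds` (tibble with 1-based
#'   `a1`, `a2` and kekulised `order`), and `smiles` (the canonical SMILES).
#' @export
mol_parse <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  can <- ob_canonical_smiles(smiles)
  if (grepl(".", can, fixed = TRUE)) {
    abort(paste0("SMILES describes more than one molecule: '", smiles, "'"),
          class = "polybiodeg_structure_error")
  }
  tok <- smiles_atom_tokens(can)
  if (nrow(tok) == 1) {
    # single-heavy-atom molecule; no bonds to perceive
    return(structure(
      list(elem = tok$elem, aromatic = tok$aromatic,
           bonds = tibble(a1 = integer(0), a2 = integer(0), order = integer(0)),
           smiles = can),
      class = "molgraph"
    ))
  }
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(can))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elems <- sub("_.*", "", rownames(ab))
  if (nrow(tok) != length(elems) || !all(tok$elem == elems)) {
    abort(paste0("internal atom-order mismatch parsing '", can, "'"),
          class = "polybiodeg_structure_error")
  }
  bonds <- tibble(
    a1 = as.integer(bb[, 1]),
    a2 = as.integer(bb[, 2]),
    order = as.integer(bb[, 3])
  )
  g <- structure(
    list(elem = elems, aromatic = tok$aromatic, bonds = bonds, smiles = can),
    class = "molgraph"
  )
  g
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$smiles, "\n  ", mol_n_atoms(x), " heavy atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Number of heavy atoms in a molecular graph
#' @param g a `molgraph`.
#' @return integer atom count.
#' @export
mol_n_atoms <- function(g) length(g$elem)

mol_neighbors <- function(g, i) {
  b <- g$bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

mol_bond_order <- function(g, i, j) {
  b <- g$bonds
  hit <- (b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i)
  if (!any(hit)) return(0L)
  b$order[which(hit)[1]]
}

mol_degree <- function(g, i) length(mol_neighbors(g, i))

# TRUE if bond k lies in a ring (endpoint still reachable with bond removed)
mol_bond_in_ring <- function(g, k) {
  b <- g$bonds[-k, , drop = FALSE]
  from <- g$bonds$a1[k]
  to <- g$bonds$a2[k]
  seen <- from
  frontier <- from
  while (length(frontier) > 0) {
    nxt <- unique(c(b$a2[b$a1 %in% frontier], b$a1[b$a2 %in% frontier]))
    nxt <- setdiff(nxt, seen)
    if (to %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  FALSE
}

# --- graph editing ----------------------------------------------------------

mol_combine <- function(g1, g2) {
  off <- mol_n_atoms(g1)
  bonds <- bind_rows(g1$bonds, mutate(g2$bonds, a1 = .data$a1 + off, a2 = .data$a2 + off))
  structure(
    list(elem = c(g1$elem, g2$elem), aromatic = c(g1$aromatic, g2$aromatic),
         bonds = bonds, smiles = NULL),
    class = "molgraph"
  )
}

mol_delete_atoms <- function(g, idx) {
  if (length(idx) == 0) return(g)
  keep <- setdiff(seq_len(mol_n_atoms(g)), idx)
  map <- integer(mol_n_atoms(g))
  map[keep] <- seq_along(keep)
  bonds <- g$bonds %>%
    filter(!(.data$a1 %in% idx) & !(.data$a2 %in% idx)) %>%
    mutate(a1 = map[.data$a1], a2 = map[.data$a2])
  structure(
    list(elem = g$elem[keep], aromatic = g$aromatic[keep], bonds = bonds, smiles = NULL),
    class = "molgraph"
  )
}

mol_add_bond <- function(g, i, j, order = 1L) {
  g$bonds <- bind_rows(g$bonds, tibble(a1 = as.integer(i), a2 = as.integer(j),
                                       order = as.integer(order)))
  g$smiles <- NULL
  g
}

mol_delete_bond <- function(g, i, j) {
  b <- g$bonds
  hit <- (b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i)
  if (!any(hit)) abort("no such bond")
  g$bonds <- b[-which(hit)[1], , drop = FALSE]
  g$smiles <- NULL
  g
}

# --- serialisation ----------------------------------------------------------

# minimal V2000 molblock; coordinates are zero, OpenBabel re-perceives
mol_to_molblock <- function(g) {
  na <- mol_n_atoms(g)
  nb <- nrow(g$bonds)
  header <- c("", "  polybiodeg", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, g$elem)
  bonds <- sprintf("%3d%3d%3d  0  0  0  0", g$bonds$a1, g$bonds$a2, g$bonds$order)
  paste(c(header, atoms, bonds, "M  END", "$$$$"), collapse = "\n")
}

#' Canonical SMILES of a molecular graph
#' @param g a `molgraph`.
#' @return a canonical SMILES string.
#' @export
mol_to_smiles <- function(g) {
  if (!is.null(g$smiles)) return(g$smiles)
  out <- ChemmineOB::convertFormat("SDF", "CAN", source = mol_to_molblock(g))
  out <- trimws(sub("\t.*", "", strsplit(out, "\n", fixed = TRUE)[[1]][1]))
  if (is.na(out) || !nzchar(out)) abort("could not serialise molecular graph",
                                        class = "polybiodeg_structure_error")
  out
}

# --- functional-group perception -------------------------------------------

# oxygens carrying an (implicit) hydrogen: degree-1 O single-bonded to carbon,
# excluding carboxylic OH (carbon also double-bonded to another O)
mol_hydroxyl_oxygens <- function(g, include_acid = FALSE) {
  idx <- which(g$elem == "O" & !g$aromatic)
  keep <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    nb <- mol_neighbors(g, i)
    if (length(nb) != 1) next
    if (g$elem[nb] != "C") next
    if (mol_bond_order(g, i, nb) != 1) next
    if (!include_acid && mol_is_carboxyl_carbon(g, nb)) next
    keep[k] <- TRUE
  }
  idx[keep]
}

mol_is_carboxyl_carbon <- function(g, i) {
  if (g$elem[i] != "C") return(FALSE)
  nb <- mol_neighbors(g, i)
  has_dbl_o <- any(vapply(nb, function(j) g$elem[j] == "O" && mol_bond_order(g, i, j) == 2,
                          logical(1)))
  has_dbl_o
}

# carboxylic acid groups: tibble(carbonyl_c, oh_o)
mol_carboxyl_groups <- function(g) {
  out <- list()
  for (i in which(g$elem == "C")) {
    nb <- mol_neighbors(g, i)
    os <- nb[g$elem[nb] == "O"]
    if (length(os) < 2) next
    dbl <- os[vapply(os, function(j) mol_bond_order(g, i, j) == 2, logical(1))]
    oh <- os[vapply(os, function(j) {
      mol_bond_order(g, i, j) == 1 && mol_degree(g, j) == 1
    }, logical(1))]
    if (length(dbl) >= 1 && length(oh) >= 1) {
      out[[length(out) + 1]] <- tibble(carbonyl_c = i, oh_o = oh[1])
    }
  }
  if (length(out) == 0) return(tibble(carbonyl_c = integer(0), oh_o = integer(0)))
  bind_rows(out)
}

# methyl ester groups: tibble(carbonyl_c, ester_o, methyl_c)
mol_methyl_ester_groups <- function(g) {
  out <- list()
  for (i in which(g$elem == "C")) {
    nb <- mol_neighbors(g, i)
    os <- nb[g$elem[nb] == "O"]
    dbl <- os[vapply(os, function(j) mol_bond_order(g, i, j) == 2, logical(1))]
    if (length(dbl) == 0) next
    single <- os[vapply(os, function(j) mol_bond_order(g, i, j) == 1, logical(1))]
    for (o in single) {
      other <- setdiff(mol_neighbors(g, o), i)
      if (length(other) == 1 && g$elem[other] == "C" && mol_degree(g, other) == 1) {
        out[[length(out) + 1]] <- tibble(carbonyl_c = i, ester_o = o, methyl_c = other)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(carbonyl_c = integer(0), ester_o = integer(0), methyl_c = integer(0)))
  }
  bind_rows(out)
}

# ring (lactone) ester linkages: tibble(carbonyl_c, ester_o) where the
# C(=O)-O single bond lies in a ring
mol_ring_esters <- function(g) {
  out <- list()
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$a1[k]; j <- g$bonds$a2[k]
    if (g$bonds$order[k] != 1) next
    if (g$elem[i] == "O" && g$elem[j] == "C") { tmp <- i; i <- j; j <- tmp }
    if (!(g$elem[i] == "C" && g$elem[j] == "O")) next
    if (!mol_is_carboxyl_carbon(g, i)) next
    if (mol_degree(g, j) != 2) next
    if (!mol_bond_in_ring(g, k)) next
    out[[length(out) + 1]] <- tibble(carbonyl_c = i, ester_o = j)
  }
  if (length(out) == 0) return(tibble(carbonyl_c = integer(0), ester_o = integer(0)))
  bind_rows(out) %>% arrange(.data$carbonyl_c, .data$ester_o)
}

# terminal hydroxyl count on a built chain (free OH, not acid OH)
mol_count_free_oh <- function(g) length(mol_hydroxyl_oxygens(g))

mol_count_cooh <- function(g) nrow(mol_carboxyl_groups(g))
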