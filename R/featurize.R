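# Featurisation of trimer structures: hashed linear-path fingerprints with a
# full bit -> fragment/atom trace, and a molecular-descriptor battery.

the_mol_cache <- new.env(parent = emptyenv())

cached_mol <- function(smiles) {
  key <- smiles
  g <- the_mol_cache[[key]]
  if (is.null(g)) {
    g <- mol_parse(smiles)
    the_mol_cache[[key]] <- g
  }
  g
}

#' Fingerprint configuration
#'
#' Hashed subgraph fingerprints over the heavy-atom graph, in the style of
#' the classic Daylight/RDKit path fingerprint: every connected subgraph of
#' 1 to `max_path` bonds (linear and branched) is enumerated, reduced to a
#' canonical fragment string, hashed (FNV-1a) and folded into `n_bits` bits.
#' The tuning grid restricts both parameters; pass `strict = FALSE` to leave
#' the grid.
#'
#' @param n_bits fingerprint length; one of 2048, 4096, 8192.
#' @param max_path maximum path length in bonds; one of 4, 5, 6.
#' @param strict enforce the tuning-grid values (default `TRUE`).
#' @return an `fp_config` object.
#' @export
fp_config <- function(n_bits = 2048, max_path = 5, strict = TRUE) {
  if (strict && (!n_bits %in% c(2048, 4096, 8192) || !max_path %in% c(4, 5, 6))) {
    abort("n_bits must be one of 2048/4096/8192 and max_path one of 4/5/6 (set strict = FALSE to override)",
          class = "polybiodeg_contract_error")
  }
  stopifnot(n_bits >= 2, max_path >= 1)
  structure(list(n_bits = as.integer(n_bits), max_path = as.integer(max_path),
                 min_path = 1L),
            class = "fp_config")
}

#' @export
print.fp_config <- function(x, ...) {
  cat("<fp_config> ", x$n_bits, " bits, paths 1-", x$max_path, " bonds\n", sep = "")
  invisible(x)
}

# atom/bond codes for path enumeration: heavy atoms only, elements lowercased
# when aromatic; bonds "-", "=", "#" or ":" (ring bond between aromatic atoms)
mol_path_codes <- function(g) {
  atom_codes <- ifelse(g$aromatic, tolower(g$elem), g$elem)
  nb <- nrow(g$bonds)
  bond_codes <- character(nb)
  for (k in seq_len(nb)) {
    i <- g$bonds$a1[k]; j <- g$bonds$a2[k]
    if (g$aromatic[i] && g$aromatic[j] && mol_bond_in_ring(g, k)) {
      bond_codes[k] <- ":"
    } else {
      bond_codes[k] <- c("-", "=", "#")[g$bonds$order[k]]
    }
  }
  list(atom_codes = atom_codes, bond_codes = bond_codes)
}

smiles_column <- function(x) {
  if (is.character(x)) return(x)
  if (inherits(x, "trimer_structure")) return(x$smiles)
  if (is.data.frame(x)) {
    for (col in c("trimer_smiles", "smiles")) {
      if (col %in% names(x)) return(x[[col]])
    }
    abort("data frame must have a 'trimer_smiles' or 'smiles' column",
          class = "polybiodeg_contract_error")
  }
  if (is.list(x)) return(vapply(x, function(t) t$smiles, character(1)))
  abort("cannot extract SMILES from input", class = "polybiodeg_contract_error")
}

#' Fingerprint a set of trimers
#'
#' @param x trimer input: a character vector of SMILES, a data frame with a
#'   `trimer_smiles`/`smiles` column, or a list of `trimer_structure`s.
#' @param cfg an [fp_config()].
#' @return a `feature_matrix` (kind "fingerprint"): binary sample-by-bit
#'   matrix plus, per sample, a trace tibble mapping every set bit to the
#'   canonical path string(s) and atom indices that set it.
#' @export
fingerprint <- function(x, cfg = fp_config()) {
  smiles <- smiles_column(x)
  n <- length(smiles)
  mat <- matrix(0L, n, cfg$n_bits,
                dimnames = list(NULL, paste0("b", seq_len(cfg$n_bits))))
  traces <- vector("list", n)
  uniq <- unique(smiles)
  uniq_hits <- vector("list", length(uniq))
  names(uniq_hits) <- uniq
  for (s in uniq) {
    g <- tryCatch(cached_mol(s), error = function(e) {
      abort(paste0("sample '", s, "': ", conditionMessage(e)),
            class = "polybiodeg_structure_error")
    })
    pc <- mol_path_codes(g)
    hits <- enumerate_subgraph_bits(pc$atom_codes,
                                    as.matrix(g$bonds[, c("a1", "a2")]),
                                    pc$bond_codes, cfg$max_path, cfg$n_bits)
    uniq_hits[[s]] <- tibble(bit = hits$bit + 1L, path = as.character(hits$path),
                             atoms = hits$atoms)
  }
  for (i in seq_len(n)) {
    tr <- uniq_hits[[smiles[i]]]
    mat[i, unique(tr$bit)] <- 1L
    traces[[i]] <- tr
  }
  structure(
    list(matrix = mat, kind = "fingerprint", cfg = cfg, smiles = smiles,
         bit_trace = traces, feature_ids = colnames(mat)),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$matrix), " samples x ", ncol(x$matrix), " ",
      x$kind, " features\n", sep = "")
  invisible(x)
}

#' Molecular descriptors for a set of trimers
#'
#' Computes the descriptor battery of the chemistry toolkit (OpenBabel
#' physicochemical properties: logP, TPSA, molar refractivity, H-bond
#' donor/acceptor counts, ...) plus element, ring and functional-group
#' counts. Descriptors yielding non-finite values are masked with a warning.
#' The descriptor count is toolkit-dependent and is recorded, not asserted.
#'
#' @param x trimer input (see [fingerprint()]).
#' @return a `feature_matrix` (kind "descriptor").
#' @export
descriptors <- function(x) {
  smiles <- smiles_column(x)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  ChemmineR::cid(sdf) <- paste0("s", seq_along(smiles))
  prop <- ChemmineR::propOB(sdf)
  num_cols <- vapply(prop, is.numeric, logical(1))
  prop_mat <- as.matrix(prop[, num_cols, drop = FALSE])
  counts <- ChemmineR::atomcountMA(sdf, addH = FALSE)
  rings <- ChemmineR::rings(sdf, type = "count", arom = TRUE)
  grp <- ChemmineR::groups(sdf, groups = "fctgroup", type = "countMA")
  mat <- cbind(prop_mat, counts, as.matrix(rings), grp)
  colnames(mat) <- make.unique(colnames(mat))
  rownames(mat) <- NULL
  bad <- !is.finite(mat)
  if (any(bad)) {
    drop_cols <- unique(colnames(mat)[which(bad, arr.ind = TRUE)[, 2]])
    warn(paste0("dropping descriptors with non-finite values: ",
                paste(drop_cols, collapse = ", ")))
    mat <- mat[, !colnames(mat) %in% drop_cols, drop = FALSE]
  }
  structure(
    list(matrix = mat, kind = "descriptor", cfg = NULL, smiles = smiles,
         bit_trace = NULL, feature_ids = colnames(mat)),
    class = "feature_matrix"
  )
}

#' Remove zero-variance features
#'
#' Drops exactly the columns that are constant across the dataset and stores
#' the retained-feature mask so it can be re-applied (not re-learned) to new
#' data, e.g. on the test fold of a cross-validation split.
#'
#' @param fm a `feature_matrix` (or plain matrix).
#' @return the filtered `feature_matrix`, with a `variance_mask` field.
#' @export
variance_filter <- function(fm) {
  mat <- if (inherits(fm, "feature_matrix")) fm$matrix else as.matrix(fm)
  if (nrow(mat) < 2) {
    abort("variance filtering needs at least two samples",
          class = "polybiodeg_contract_error")
  }
  keep <- matrixStats_colVars(mat) > 0
  out <- if (inherits(fm, "feature_matrix")) fm else
    structure(list(matrix = mat, kind = "matrix", cfg = NULL, smiles = NULL,
                   bit_trace = NULL, feature_ids = colnames(mat)),
              class = "feature_matrix")
  out$matrix <- mat[, keep, drop = FALSE]
  out$feature_ids <- colnames(out$matrix)
  out$variance_mask <- keep
  out
}

# column variances without an extra dependency
matrixStats_colVars <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  colSums((m - rep(mu, each = n))^2) / (n - 1)
}

#' Apply a stored variance mask to new data
#'
#' @param mat a matrix in the original (unfiltered) feature space.
#' @param mask logical retained-feature mask from [variance_filter()].
#' @return the column-subset matrix.
#' @export
apply_variance_mask <- function(mat, mask) {
  stopifnot(ncol(mat) == length(mask))
  mat[, mask, drop = FALSE]
}
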