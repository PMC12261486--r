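#' Canonicalize SMILES strings
#'
#' Maps each SMILES to a canonical form so that structurally identical
#' inputs (e.g. `"OCC"` and `"CCO"`) share one key when endpoint tables are
#' merged.  Canonicalization delegates to Open Babel's canonical-SMILES
#' writer; salts and stereochemistry are left untouched.
#'
#' With `opaque = TRUE` no chemistry is performed and the raw string is
#' returned as its own key (whitespace-trimmed).  This mode exists for
#' toolkit-free fixtures; it never merges alternative writings of the same
#' structure.
#'
#' @param smiles Character vector of SMILES strings.
#' @param opaque Logical; treat each string as an opaque key.
#' @return Character vector of canonical keys, same length as `smiles`.
#' @examples
#' canonicalize_smiles(c("OCC", "CCO"))  # both "CCO"
#' @export
canonicalize_smiles <- function(smiles, opaque = FALSE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  if (any(!nzchar(trimws(smiles)))) {
    stop_named("canonicalize_smiles: empty SMILES at row %d",
               which(!nzchar(trimws(smiles)))[1])
  }
  if (opaque) return(trimws(smiles))
  if (any(grepl("[[:space:]]", trimws(smiles)))) {
    stop_named("canonicalize_smiles: SMILES must not contain whitespace (row %d)",
               which(grepl("[[:space:]]", trimws(smiles)))[1])
  }
  inp <- paste0(trimws(smiles), " r", seq_along(smiles), collapse = "\n")
  out <- ob_convert("SMI", "CAN", paste0(inp, "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, function(p) p[2] %||% NA_character_, character(1))
  can <- vapply(parts, `[`, character(1), 1)
  res <- can[match(paste0("r", seq_along(smiles)), ids)]
  if (anyNA(res)) {
    bad <- which(is.na(res))[1]
    stop_named("canonicalize_smiles: unparsable SMILES '%s' at row %d",
               smiles[bad], bad)
  }
  res
}

# Open Babel conversion with its stderr chatter suppressed.
ob_convert <- function(from, to, text) {
  con <- file(tempfile(), open = "w+")
  sink(con, type = "message")
  on.exit({ sink(type = "message"); close(con) }, add = TRUE)
  ChemmineOB::convertFormat(from, to, text)
}

# Parse molecules into atom/bond graphs via Open Babel's V2000 output.
# Returns a list per molecule: elem (character), bonds (m x 3 matrix:
# atom1, atom2, order).  Single-atom molecules are handled (no bond block).
parse_mol_graphs <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  inp <- paste0(trimws(smiles), " r", seq_along(smiles), collapse = "\n")
  out <- ob_convert("SMI", "SDF", paste0(inp, "\n"))
  blocks <- strsplit(out, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  graphs <- vector("list", length(smiles))
  got <- character(length(blocks))
  for (i in seq_along(blocks)) {
    ln <- strsplit(blocks[i], "\n", fixed = TRUE)[[1]]
    if (!nzchar(ln[1]) && length(ln) > 1) ln <- ln[-1]
    title <- trimws(ln[1])
    counts <- ln[4]
    na <- as.integer(substr(counts, 1, 3))
    nb <- as.integer(substr(counts, 4, 6))
    atoms <- ln[5:(4 + na)]
    elem <- trimws(substr(atoms, 32, 34))
    if (nb > 0) {
      bl <- ln[(5 + na):(4 + na + nb)]
      bonds <- cbind(as.integer(substr(bl, 1, 3)),
                     as.integer(substr(bl, 4, 6)),
                     as.integer(substr(bl, 7, 9)))
    } else {
      bonds <- matrix(integer(0), ncol = 3)
    }
    got[i] <- title
    graphs[[i]] <- list(elem = elem, bonds = bonds)
  }
  idx <- match(paste0("r", seq_along(smiles)), got)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop_named("parse_mol_graphs: unparsable SMILES '%s' at row %d",
               smiles[bad], bad)
  }
  graphs[idx]
}

#' Fingerprint configuration
#'
#' @param radius Neighborhood radius of the circular fingerprint
#'   (`radius = 2` corresponds to ECFP4-style environments).
#' @param n_bits Length of the folded binary vector.
#' @param opaque Logical; hash the raw key string into bits instead of
#'   computing substructure environments (toolkit-free fixture mode).
#' @return A list of class `fp_config`.
#' @export
fp_config <- function(radius = 2L, n_bits = 2048L, opaque = FALSE) {
  stopifnot(radius >= 0, n_bits > 0)
  structure(list(radius = as.integer(radius), n_bits = as.integer(n_bits),
                 opaque = isTRUE(opaque)),
            class = "fp_config")
}

#' Compute binary substructure fingerprints
#'
#' Circular (Morgan-style) fingerprints: each atom starts from an invariant
#' built from its element, heavy-atom degree and bond-order sum; the
#' invariant is then iteratively rehashed with the sorted
#' (bond order, neighbor invariant) pairs of its neighbors up to
#' `cfg$radius` shells.  Every distinct environment identifier across all
#' shells sets one bit after folding modulo `cfg$n_bits` (set semantics: a
#' bit is 0/1, never a count).  Featurization is deterministic per molecule.
#'
#' In opaque mode each key is hashed into a fixed pseudo-random bit pattern;
#' identical strings map to identical vectors but no substructure meaning
#' attaches to the bits.
#'
#' @param smiles Character vector of (ideally canonical) SMILES, or opaque
#'   keys when `cfg$opaque`.
#' @param cfg An [fp_config()].
#' @return Integer 0/1 matrix, `length(smiles)` x `cfg$n_bits`.
#' @export
featurize_fingerprint <- function(smiles, cfg = fp_config()) {
  stopifnot(inherits(cfg, "fp_config"))
  n <- length(smiles)
  X <- matrix(0L, n, cfg$n_bits)
  if (n == 0L) return(X)
  if (any(!nzchar(trimws(smiles)))) {
    stop_named("featurize_fingerprint: empty key at row %d",
               which(!nzchar(trimws(smiles)))[1])
  }
  if (cfg$opaque) {
    nfill <- max(8L, cfg$n_bits %/% 16L)
    for (i in seq_len(n)) {
      h0 <- fnv1a32(smiles[i])
      bits <- unique(vapply(seq_len(nfill), function(j)
        hash_ints(c(h0, j)) %% cfg$n_bits, numeric(1)))
      X[i, bits + 1] <- 1L
    }
    return(X)
  }
  graphs <- parse_mol_graphs(smiles)
  for (i in seq_len(n)) {
    ids <- morgan_ids(graphs[[i]], cfg$radius)
    X[i, unique(ids %% cfg$n_bits) + 1] <- 1L
  }
  X
}

# Distinct environment identifiers of one molecule up to the given radius.
morgan_ids <- function(g, radius) {
  na <- length(g$elem)
  elem_code <- vapply(g$elem, function(e) hash_ints(utf8ToInt(e)), numeric(1))
  deg <- integer(na)
  bsum <- integer(na)
  nbr <- vector("list", na)
  if (nrow(g$bonds) > 0) {
    for (r in seq_len(nrow(g$bonds))) {
      a <- g$bonds[r, 1]; b <- g$bonds[r, 2]; o <- g$bonds[r, 3]
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      bsum[a] <- bsum[a] + o; bsum[b] <- bsum[b] + o
      nbr[[a]] <- rbind(nbr[[a]], c(b, o))
      nbr[[b]] <- rbind(nbr[[b]], c(a, o))
    }
  }
  inv <- vapply(seq_len(na), function(i)
    hash_ints(c(elem_code[i], deg[i], bsum[i])), numeric(1))
  ids <- inv
  if (radius > 0) {
    for (r in seq_len(radius)) {
      newinv <- inv
      for (i in seq_len(na)) {
        if (is.null(nbr[[i]])) next
        pairs <- cbind(nbr[[i]][, 2], inv[nbr[[i]][, 1]])
        ord <- order(pairs[, 1], pairs[, 2])
        newinv[i] <- hash_ints(c(r, inv[i], t(pairs[ord, , drop = FALSE])))
      }
      inv <- newinv
      ids <- c(ids, inv)
    }
  }
  unique(ids)
}
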