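# Binary molecular fingerprints.  All four types are pure functions of the
# molecular graph (plus stereo/charge for the enhanced type): atom input
# order and atom-map numbers never influence any bit.  Bit positions come
# from the package's fixed polynomial string hash, so vectors are identical
# across runs and platforms.

FP_TYPES <- c("circular", "extended", "substructure", "enhanced")

FP_DEFAULT_LENGTH <- c(circular = 1024L, extended = 1024L,
                       substructure = 307L, enhanced = 1024L)

# extension block carrying charge/stereo signatures of the enhanced type
ENHANCED_EXT_BITS <- 64L

new_fingerprint <- function(bits, fp_type) {
  structure(list(bits = bits, length = length(bits), fp_type = fp_type),
            class = "rs_fp")
}

#' @export
print.rs_fp <- function(x, ...) {
  cat(sprintf("<rs_fp %s> %d/%d bits set\n", x$fp_type, sum(x$bits), x$length))
  invisible(x)
}

# canonical atom label used in environment and path strings
fp_atom_label <- function(mol, i) {
  a <- mol$atoms[i, ]
  lab <- if (a$aromatic) tolower(a$symbol) else a$symbol
  if (a$charge != 0) lab <- paste0(lab, sprintf("%+d", a$charge))
  lab
}

fp_bond_label <- function(b) {
  if (b$aromatic) ":" else if (b$order == 2) "=" else if (b$order == 3) "#" else "-"
}

# per-atom invariant and radius-1 environment strings
atom_environments <- function(mol) {
  adj <- adjacency_list(mol)
  bmap <- bond_index_map(mol)
  in_ring <- ring_atom_flags(mol)
  inv <- vapply(seq_len(n_atoms(mol)), function(i) {
    paste(fp_atom_label(mol, i), lengths(adj)[i], mol$atoms$charge[i],
          mol$atoms$hcount[i], as.integer(in_ring[i]), sep = "|")
  }, "")
  env1 <- vapply(seq_len(n_atoms(mol)), function(i) {
    if (!length(adj[[i]])) return(inv[i])  # isolated atom: radii collapse
    nb <- vapply(adj[[i]], function(j) {
      k <- bmap[paste(min(i, j), max(i, j), sep = "-")]
      paste0(fp_bond_label(mol$bonds[k, ]), inv[j])
    }, "")
    paste0(inv[i], "(", paste(sort(nb), collapse = ","), ")")
  }, "")
  list(inv = inv, env1 = env1)
}

set_bits <- function(strings, length) {
  bits <- logical(length)
  if (length(strings)) bits[rs_hash_bit(strings, length)] <- TRUE
  bits
}

#' Circular fingerprint (radius 1)
#'
#' Hashed circular atom environments of radius 0 and 1 (an atom's invariant
#' and the invariant together with its immediate bonded neighbourhood),
#' folded to `length` bits.  Functionally an ECFP-2-style fingerprint.
#'
#' @param mol an `rs_mol`.
#' @param length fingerprint length in bits.
#' @return an `rs_fp`.
#' @export
circular_fingerprint <- function(mol, length = 1024L) {
  env <- atom_environments(mol)
  strings <- unique(c(paste0("C0|", env$inv), paste0("C1|", env$env1)))
  # an isolated atom's radius-0 and radius-1 environments collapse to one bit
  iso <- !lengths(adjacency_list(mol))
  if (any(iso)) {
    strings <- setdiff(strings, paste0("C1|", env$env1[iso]))
  }
  new_fingerprint(set_bits(strings, length), "circular")
}

# all simple linear paths up to max_depth bonds, as canonical label strings
molecule_paths <- function(mol, max_depth = 7L) {
  adj <- adjacency_list(mol)
  bmap <- bond_index_map(mol)
  alab <- vapply(seq_len(n_atoms(mol)), function(i) fp_atom_label(mol, i), "")
  paths <- character(0)
  walk <- function(v, labels, on_path) {
    fwd <- paste(labels, collapse = "")
    bwd <- paste(rev(labels), collapse = "")
    paths[[length(paths) + 1]] <<- if (fwd <= bwd) fwd else bwd
    if ((length(labels) - 1) / 2 >= max_depth) return()
    for (w in adj[[v]]) {
      if (on_path[w]) next
      k <- bmap[paste(min(v, w), max(v, w), sep = "-")]
      on_path[w] <- TRUE
      walk(w, c(labels, fp_bond_label(mol$bonds[k, ]), alab[w]), on_path)
      on_path[w] <- FALSE
    }
  }
  for (s in seq_len(n_atoms(mol))) {
    on <- logical(n_atoms(mol)); on[s] <- TRUE
    walk(s, alab[s], on)
  }
  unique(unlist(paths))
}

#' Extended fingerprint (paths plus ring descriptors)
#'
#' Hashed linear atom/bond paths up to `max_path_depth` bonds, augmented with
#' ring-system descriptor bits (each ring size present and the ring count),
#' folded into one vector.  The default length is 1024 bits.
#'
#' @param mol an `rs_mol`.
#' @param length fingerprint length in bits.
#' @param max_path_depth maximum path length in bonds.
#' @return an `rs_fp`.
#' @export
extended_fingerprint <- function(mol, length = 1024L, max_path_depth = 7L) {
  strings <- paste0("E|", molecule_paths(mol, max_path_depth))
  ri <- ring_info(mol)
  if (length(ri$sizes)) strings <- c(strings, paste0("E|RING:", ri$sizes))
  if (ri$n_rings > 0) strings <- c(strings, paste0("E|NRINGS:", ri$n_rings))
  new_fingerprint(set_bits(strings, length), "extended")
}

# Substructure keys ------------------------------------------------------------

.reactsim_env <- new.env(parent = emptyenv())

#' Load the bundled substructure key set
#'
#' Returns the 307 SMARTS keys that define the substructure fingerprint, as a
#' character vector in bit order.  The bundled set is a synthetic stand-in
#' curated for this package (functional groups plus systematic element, bond
#' and ring patterns); see the vignette.  A user file (one SMARTS per line,
#' `#` comments allowed) can be supplied instead.
#'
#' @param path optional path to an alternative key file.
#' @return character vector of 307 SMARTS patterns.
#' @export
substructure_keys <- function(path = NULL) {
  cache_key <- path %||% "__bundled__"
  cached <- .reactsim_env$keys[[cache_key]]
  if (!is.null(cached)) return(cached)
  if (is.null(path)) {
    path <- system.file("extdata", "substructure_keys_synthetic_307.smarts",
                        package = "reactsim")
    if (!nzchar(path))
      path <- file.path("inst", "extdata", "substructure_keys_synthetic_307.smarts")
  }
  if (!file.exists(path))
    rs_error(sprintf("substructure key file not found: %s (expected 307 SMARTS)", path),
             "rs_config_error")
  keys <- readLines(path)
  keys <- trimws(keys)
  keys <- keys[nzchar(keys) & !startsWith(keys, "#")]
  if (length(keys) != 307)
    rs_error(sprintf("substructure key file %s has %d patterns, expected 307",
                     path, length(keys)), "rs_config_error")
  if (is.null(.reactsim_env$keys)) .reactsim_env$keys <- list()
  .reactsim_env$keys[[cache_key]] <- keys
  keys
}

# parsed-pattern cache so batch fingerprinting does not re-parse 307 SMARTS
parsed_substructure_keys <- function(path = NULL) {
  cache_key <- paste0("parsed::", path %||% "__bundled__")
  cached <- .reactsim_env$keys[[cache_key]]
  if (!is.null(cached)) return(cached)
  pats <- lapply(substructure_keys(path), parse_smarts)
  .reactsim_env$keys[[cache_key]] <- pats
  pats
}

#' Substructure-key fingerprint (307 bits)
#'
#' Bit `i` is set iff key pattern `i` has at least one match in the molecule.
#'
#' @param mol an `rs_mol`.
#' @param keys_path optional alternative key file (see [substructure_keys()]).
#' @return an `rs_fp` of length 307.
#' @export
substructure_fingerprint <- function(mol, keys_path = NULL) {
  pats <- parsed_substructure_keys(keys_path)
  ctx <- smarts_context(mol)
  bits <- vapply(pats, function(p) smarts_match_ctx(ctx, p), TRUE)
  new_fingerprint(bits, "substructure")
}

# Enhanced ---------------------------------------------------------------------

# A tetrahedral parity invariant: the stored token is relative to the stored
# neighbour order, so it is normalised against the canonical neighbour order
# (implicit H first, then neighbours by canonical rank).
canonical_parity <- function(mol, i, ranks) {
  tok <- mol$atoms$stereo[i]
  if (tok == "") return("")
  stored <- mol$chiral_order[[i]]
  nb <- setdiff(stored, 0L)
  canon <- c(if (0L %in% stored) 0L, nb[order(ranks[nb])])
  if (length(stored) != length(canon) || length(stored) < 3) return(tok)
  perm <- match(canon, stored)
  if (permutation_parity(perm) == -1L) (if (tok == "@") "@@" else "@") else tok
}

#' Enhanced fingerprint (extended plus stereo/charge signatures)
#'
#' The extended fingerprint concatenated with a dedicated 64-bit extension
#' block holding hashed signatures of (atom environment, formal charge) for
#' every charged atom, (atom environment, tetrahedral parity) for every
#' stereocentre and (bond environment, E/Z) for every stereo double bond.
#' Molecules differing only in one parity or one formal charge therefore get
#' different fingerprints, while their extended fingerprints agree.
#'
#' @param mol an `rs_mol`.
#' @param length base (extended) block length in bits; the extension block
#'   adds 64 bits.
#' @param max_path_depth maximum path length for the base block.
#' @return an `rs_fp` of length `length + 64`.
#' @export
enhanced_fingerprint <- function(mol, length = 1024L, max_path_depth = 7L) {
  base <- extended_fingerprint(mol, length, max_path_depth)
  env <- atom_environments(mol)
  sig <- character(0)
  charged <- which(mol$atoms$charge != 0)
  if (length(charged))
    sig <- c(sig, paste0("Q|", env$env1[charged], "|", mol$atoms$charge[charged]))
  stereo_atoms <- which(mol$atoms$stereo != "")
  if (length(stereo_atoms)) {
    ranks <- canonical_ranks(mol)
    # the environment string excludes the parity itself; the signature pairs
    # it with the normalised parity token
    par <- vapply(stereo_atoms, function(i) canonical_parity(mol, i, ranks), "")
    sig <- c(sig, paste0("S|", env$env1[stereo_atoms], "|", par))
  }
  ez <- which(mol$bonds$stereo != "")
  if (length(ez)) {
    for (k in ez) {
      ends <- sort(env$inv[c(mol$bonds$a1[k], mol$bonds$a2[k])])
      sig <- c(sig, paste0("S|", paste(ends, collapse = "="), "|",
                           mol$bonds$stereo[k]))
    }
  }
  ext <- set_bits(unique(sig), ENHANCED_EXT_BITS)
  new_fingerprint(c(base$bits, ext), "enhanced")
}

#' Compute a fingerprint by type name
#'
#' @param mol an `rs_mol`.
#' @param fp_type one of `"circular"`, `"extended"`, `"substructure"`,
#'   `"enhanced"`.
#' @param length base length in bits (ignored for `substructure`).
#' @return an `rs_fp`.
#' @export
fingerprint <- function(mol, fp_type = "extended", length = NULL) {
  if (!fp_type %in% FP_TYPES)
    rs_error(sprintf("unknown fingerprint type '%s'; valid: %s", fp_type,
                     paste(FP_TYPES, collapse = ", ")), "rs_enum_error")
  length <- length %||% FP_DEFAULT_LENGTH[[fp_type]]
  # memo keyed on the canonical SMILES: fingerprints are pure functions of
  # the molecular graph, so equal canonical forms share one computation
  key <- if (!is.na(mol$smiles)) paste(fp_type, length, mol$smiles) else NA
  if (!is.na(key)) {
    if (is.null(.reactsim_env$fp_cache))
      .reactsim_env$fp_cache <- new.env(parent = emptyenv())
    hit <- .reactsim_env$fp_cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  fp <- switch(fp_type,
               circular = circular_fingerprint(mol, length),
               extended = extended_fingerprint(mol, length),
               substructure = substructure_fingerprint(mol),
               enhanced = enhanced_fingerprint(mol, length))
  if (!is.na(key)) {
    if (base::length(ls(.reactsim_env$fp_cache)) > 20000)
      .reactsim_env$fp_cache <- new.env(parent = emptyenv())
    .reactsim_env$fp_cache[[key]] <- fp
  }
  fp
}
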