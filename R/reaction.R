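# Reaction container and readers: reaction SMILES ("subs>>prods", optional
# agents field ignored), MDL RXN V2000, and TSV/CSV batch tables.

#' Construct a reaction object
#'
#' @param substrates,products lists of `rs_mol`.
#' @param id identifier string.
#' @param ec optional EC number string (1-4 dot-separated fields), stored
#'   verbatim.
#' @return an object of class `rs_reaction` with a `mapped` flag: `TRUE` iff
#'   every heavy atom on the substrate side carries a nonzero atom-map number
#'   matched exactly once on the product side.
#' @export
new_reaction <- function(substrates, products, id = NA_character_, ec = NA_character_) {
  if (!length(substrates) || !length(products))
    rs_error("a reaction needs at least one substrate and one product",
             "rs_validation_error")
  for (side in list(substrates, products)) {
    maps <- unlist(lapply(side, function(m) m$atoms$map))
    maps <- maps[maps > 0]
    if (anyDuplicated(maps))
      rs_error("duplicate nonzero atom-map number within one reaction side",
               "rs_mapping_error")
  }
  smaps <- unlist(lapply(substrates, function(m) m$atoms$map))
  pmaps <- unlist(lapply(products, function(m) m$atoms$map))
  mapped <- all(smaps > 0) && all(pmaps > 0) &&
    identical(sort(smaps), sort(pmaps))
  structure(list(id = id, substrates = substrates, products = products,
                 ec = ec, mapped = mapped),
            class = "rs_reaction")
}

#' @export
print.rs_reaction <- function(x, ...) {
  cat(sprintf("<rs_reaction> %s: %d substrate(s) >> %d product(s)%s%s\n",
              if (is.na(x$id)) "(unnamed)" else x$id,
              length(x$substrates), length(x$products),
              if (x$mapped) ", atom-mapped" else "",
              if (!is.na(x$ec)) paste0(", EC ", x$ec) else ""))
  invisible(x)
}

#' Parse a reaction from reaction SMILES or an MDL RXN V2000 block
#'
#' Reaction SMILES is `substrates>>products` (or `substrates>agents>products`;
#' the agents field is ignored).  Dot-separated components become separate
#' molecules; input side order is preserved.  A multi-line string starting
#' with `$RXN` is read as MDL RXN V2000.
#'
#' @param text reaction SMILES string or RXN V2000 text.
#' @param id,ec optional identifier and EC number.
#' @return an `rs_reaction`.
#' @examples
#' r <- parse_reaction("[CH3:1][OH:2]>>[CH3:1][OH:2]")
#' r$mapped
#' @export
parse_reaction <- function(text, id = NA_character_, ec = NA_character_) {
  if (!is.character(text) || length(text) != 1 || is.na(text))
    rs_error("reaction input must be a single string", "rs_format_error")
  if (grepl("^\\s*\\$RXN", text)) return(parse_rxn_block(text, id = id, ec = ec))
  parts <- strsplit(text, ">", fixed = TRUE)[[1]]
  if (length(parts) == 2) { subs <- parts[1]; prods <- parts[2] }
  else if (length(parts) == 3) { subs <- parts[1]; prods <- parts[3] }
  else rs_error("reaction SMILES must contain '>>' (or 'subs>agents>prods')",
                "rs_format_error")
  if (!nzchar(trimws(subs)) || !nzchar(trimws(prods)))
    rs_error("reaction side is empty", "rs_validation_error")
  split_side <- function(s) {
    comps <- strsplit(trimws(s), ".", fixed = TRUE)[[1]]
    comps <- comps[nzchar(comps)]
    lapply(comps, parse_molecule)
  }
  new_reaction(split_side(subs), split_side(prods), id = id, ec = ec)
}

#' Serialize a reaction to reaction SMILES
#' @param rxn an `rs_reaction`.
#' @return a reaction SMILES string.
#' @export
serialize_reaction <- function(rxn) {
  paste0(paste(vapply(rxn$substrates, serialize_molecule, ""), collapse = "."),
         ">>",
         paste(vapply(rxn$products, serialize_molecule, ""), collapse = "."))
}

# MDL RXN V2000 ----------------------------------------------------------------

parse_rxn_block <- function(text, id = NA_character_, ec = NA_character_) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (!grepl("^\\s*\\$RXN", lines[1]))
    rs_error("not an RXN block", "rs_format_error")
  counts_line <- lines[5]
  ns <- suppressWarnings(as.integer(substr(counts_line, 1, 3)))
  np <- suppressWarnings(as.integer(substr(counts_line, 4, 6)))
  if (is.na(ns) || is.na(np))
    rs_error("bad RXN counts line", "rs_format_error")
  mol_starts <- which(grepl("^\\$MOL", lines))
  if (length(mol_starts) != ns + np)
    rs_error(sprintf("RXN declares %d molecules but has %d $MOL blocks",
                     ns + np, length(mol_starts)), "rs_format_error")
  mol_ends <- c(mol_starts[-1] - 1L, length(lines))
  mols <- lapply(seq_along(mol_starts), function(q) {
    parse_molfile(lines[(mol_starts[q] + 1L):mol_ends[q]])
  })
  new_reaction(mols[seq_len(ns)], mols[ns + seq_len(np)], id = id, ec = ec)
}

# V2000 molfile body (without the $MOL line)
parse_molfile <- function(lines) {
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na)) rs_error("bad molfile counts line", "rs_format_error")
  atom_lines <- lines[4 + seq_len(na)]
  sym <- trimws(substr(atom_lines, 32, 34))
  amap <- suppressWarnings(as.integer(substr(atom_lines, 61, 63)))
  amap[is.na(amap)] <- 0L
  atoms <- data.frame(symbol = sym, aromatic = FALSE, charge = 0L,
                      hcount = NA_integer_, map = amap, stereo = "",
                      stringsAsFactors = FALSE)
  bonds <- empty_bonds()
  if (nb > 0) {
    bond_lines <- lines[4 + na + seq_len(nb)]
    for (bl in bond_lines) {
      i <- as.integer(substr(bl, 1, 3)); j <- as.integer(substr(bl, 4, 6))
      t <- as.integer(substr(bl, 7, 9))
      aromatic <- !is.na(t) && t == 4
      order <- if (aromatic) 1 else t
      bonds[nrow(bonds) + 1, ] <- list(i, j, order, aromatic, "", "")
    }
  }
  for (ln in lines[grepl("^M  CHG", lines)]) {
    toks <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    ncg <- toks[1]
    for (q in seq_len(ncg)) {
      atoms$charge[toks[2 * q]] <- toks[2 * q + 1]
    }
  }
  atoms$aromatic[atoms$symbol %in% c("C", "N", "O", "S", "P", "B")] <-
    atoms$aromatic[atoms$symbol %in% c("C", "N", "O", "S", "P", "B")]  # no-op; V2000 uses bond type 4
  # mark atoms aromatic if they carry an aromatic bond
  if (nrow(bonds) && any(bonds$aromatic)) {
    ar <- unique(c(bonds$a1[bonds$aromatic], bonds$a2[bonds$aromatic]))
    atoms$aromatic[ar] <- TRUE
  }
  # collapse explicit hydrogens
  hidx <- which(atoms$symbol == "H")
  if (length(hidx)) {
    keep <- setdiff(seq_len(nrow(atoms)), hidx)
    extra_h <- integer(nrow(atoms))
    drop_bond <- logical(nrow(bonds))
    for (k in seq_len(nrow(bonds))) {
      i <- bonds$a1[k]; j <- bonds$a2[k]
      if (i %in% hidx && j %in% hidx) { drop_bond[k] <- TRUE; next }
      if (i %in% hidx) { extra_h[j] <- extra_h[j] + 1L; drop_bond[k] <- TRUE }
      if (j %in% hidx) { extra_h[i] <- extra_h[i] + 1L; drop_bond[k] <- TRUE }
    }
    bonds <- bonds[!drop_bond, , drop = FALSE]
    remap <- match(seq_len(nrow(atoms)), keep)
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL
    atoms$hcount <- ifelse(is.na(atoms$hcount), NA_integer_, atoms$hcount)
    attr(atoms, "extra_h") <- extra_h[keep]
  }
  mol <- new_molecule(atoms, bonds)
  mol <- finish_molecule(mol)
  eh <- attr(atoms, "extra_h")
  if (!is.null(eh)) mol$atoms$hcount <- mol$atoms$hcount + eh
  validate_molecule(mol)
  mol$smiles <- serialize_molecule(mol)
  mol
}

#' Write a reaction as MDL RXN V2000
#' @param rxn an `rs_reaction`.
#' @param path output file path.
#' @export
write_rxn <- function(rxn, path) {
  fmt_mol <- function(mol) {
    na <- n_atoms(mol); nb <- nrow(mol$bonds)
    out <- c("$MOL", "", "  reactsim", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
    for (i in seq_len(na)) {
      out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0%3d  0  0",
                            0, 0, 0, mol$atoms$symbol[i], mol$atoms$map[i]))
    }
    for (k in seq_len(nb)) {
      t <- if (mol$bonds$aromatic[k]) 4L else as.integer(mol$bonds$order[k])
      out <- c(out, sprintf("%3d%3d%3d  0  0  0  0",
                            mol$bonds$a1[k], mol$bonds$a2[k], t))
    }
    chg <- which(mol$atoms$charge != 0)
    if (length(chg)) {
      out <- c(out, paste0("M  CHG", sprintf("%3d", length(chg)),
                           paste0(sprintf("%4d%4d", chg, mol$atoms$charge[chg]),
                                  collapse = "")))
    }
    c(out, "M  END")
  }
  lines <- c("$RXN", if (is.na(rxn$id)) "" else rxn$id, "  reactsim", "",
             sprintf("%3d%3d", length(rxn$substrates), length(rxn$products)))
  for (m in c(rxn$substrates, rxn$products)) lines <- c(lines, fmt_mol(m))
  writeLines(lines, path)
  invisible(path)
}

# Batch tables ------------------------------------------------------------------

#' Read a batch reaction table (TSV/CSV)
#'
#' Expects columns `id` and `reaction` (reaction SMILES), optionally `ec`.
#' Malformed rows are skipped with a warning naming the row number, or abort
#' when `strict = TRUE`.
#'
#' @param path file path; tab- or comma-separated, chosen by file extension
#'   (`.csv` means comma) or by `sep`.
#' @param sep optional field separator override.
#' @param strict abort on the first malformed row instead of skipping.
#' @return a list of `rs_reaction`, in file order.
#' @export
read_reaction_table <- function(path, sep = NULL, strict = FALSE) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (!all(c("id", "reaction") %in% names(df)))
    rs_error("reaction table must have columns 'id' and 'reaction'",
             "rs_config_error")
  has_ec <- "ec" %in% names(df)
  out <- list()
  for (r in seq_len(nrow(df))) {
    rxn <- tryCatch(
      parse_reaction(df$reaction[r], id = as.character(df$id[r]),
                     ec = if (has_ec && nzchar(df$ec[r] %||% ""))
                       as.character(df$ec[r]) else NA_character_),
      error = function(e) e)
    if (inherits(rxn, "error")) {
      msg <- sprintf("row %d (%s): %s", r, df$id[r], conditionMessage(rxn))
      if (strict) rs_error(msg, "rs_format_error")
      rs_warn(paste("skipping", msg))
      next
    }
    out[[length(out) + 1]] <- rxn
  }
  out
}

#' Write reactions as a batch TSV
#' @param reactions list of `rs_reaction`.
#' @param path output path.
#' @export
write_reaction_table <- function(reactions, path) {
  df <- data.frame(
    id = vapply(reactions, function(r) r$id %||% NA_character_, ""),
    reaction = vapply(reactions, serialize_reaction, ""),
    ec = vapply(reactions, function(r) r$ec %||% NA_character_, ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
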