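# SMILES reader / writer for the organic subset plus bracket atoms, with
# atom-map numbers, formal charges, tetrahedral parity tokens and directional
# (cis/trans) bonds.  Hydrogens are implicit: explicit [H] atoms and bracket
# H-counts are collapsed onto heavy atoms at parse time.

BRACKET_RE <- paste0(
  "^\\[(\\d+)?",                       # isotope (accepted, ignored)
  "([A-Z][a-z]?|[a-z]|\\*)",           # element symbol (lowercase = aromatic)
  "(@@|@)?",                           # tetrahedral parity
  "(H\\d*)?",                          # hydrogen count
  "(\\+\\d+|-\\d+|\\++|-+)?",          # formal charge
  "(?::(\\d+))?",                      # atom-map number
  "\\]"
)

#' Parse a SMILES string into a molecule
#'
#' Reads one connected molecule written in SMILES.  Formal charges, aromatic
#' (lowercase) atoms, tetrahedral parity (`@`/`@@`), directional bonds
#' (`/`, `\\`) and atom-map numbers (`[CH3:1]`) are preserved; hydrogens stay
#' implicit.  Kekule-written benzene rings are aromatised so that both ways of
#' writing an aromatic ring give identical downstream fingerprints.
#'
#' @param text a SMILES string for a single connected molecule.
#' @return an object of class `rs_mol`.
#' @examples
#' m <- parse_molecule("[CH3:1][OH:2]")
#' m$atoms$map
#' @export
parse_molecule <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text))
    rs_error("SMILES input must be a single non-empty string", "rs_format_error")
  mol <- parse_smiles_component(text)
  mol <- finish_molecule(mol)
  validate_molecule(mol, require_connected = TRUE)
  mol$smiles <- serialize_molecule(mol)
  mol
}

# core recursive-descent SMILES parser for one dot-free component
parse_smiles_component <- function(text) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  pos <- 1L

  atoms <- list()
  bonds <- empty_bonds()
  chiral_order <- list()
  nbr_order <- list()      # neighbour registration order per atom
  stack <- integer(0)      # open-branch previous atoms
  prev <- NA_integer_
  pending_bond <- ""       # bond token awaiting next atom
  ring_open <- list()      # ring number -> list(atom, bond, slotpos)

  fail <- function(what) {
    rs_error(sprintf("SMILES parse failure at position %d ('%s'): %s",
                     pos, substr(text, pos, min(n, pos + 4)), what),
             "rs_format_error")
  }

  add_atom <- function(symbol, aromatic, charge, hcount, map, stereo, hexplicit) {
    atoms[[length(atoms) + 1]] <<- list(
      symbol = symbol, aromatic = aromatic, charge = charge,
      hcount = hcount, map = map, stereo = stereo, hexplicit = hexplicit)
    nbr_order[[length(atoms)]] <<- integer(0)
    length(atoms)
  }

  add_bond <- function(i, j, token) {
    aromatic <- FALSE; order <- 1; updown <- ""
    if (token == "") {
      if (atoms[[i]]$aromatic && atoms[[j]]$aromatic) aromatic <- TRUE
    } else if (token == "-") order <- 1
    else if (token == "=") order <- 2
    else if (token == "#") order <- 3
    else if (token == ":") aromatic <- TRUE
    else if (token == "/" || token == "\\") { order <- 1; updown <- token }
    else fail(sprintf("unknown bond token '%s'", token))
    bonds[nrow(bonds) + 1, ] <<- list(i, j, order, aromatic, updown, "")
    nbr_order[[i]] <<- c(nbr_order[[i]], j)
    nbr_order[[j]] <<- c(nbr_order[[j]], i)
  }

  handle_ring <- function(num, cur, token) {
    key <- as.character(num)
    if (is.null(ring_open[[key]])) {
      # reserve the neighbour slot now; filled at closure
      nbr_order[[cur]] <<- c(nbr_order[[cur]], -num)
      ring_open[[key]] <<- list(atom = cur, bond = token)
    } else {
      op <- ring_open[[key]]
      if (op$atom == cur) fail("ring closure to the same atom")
      token2 <- if (nzchar(token)) token else op$bond
      aromatic <- FALSE; order <- 1; updown <- ""
      if (token2 == "") {
        if (atoms[[op$atom]]$aromatic && atoms[[cur]]$aromatic) aromatic <- TRUE
      } else if (token2 == "=") order <- 2
      else if (token2 == "#") order <- 3
      else if (token2 == ":") aromatic <- TRUE
      else if (token2 == "/" || token2 == "\\") updown <- token2
      bonds[nrow(bonds) + 1, ] <<- list(op$atom, cur, order, aromatic, updown, "")
      slot <- which(nbr_order[[op$atom]] == -num)[1]
      nbr_order[[op$atom]][slot] <<- cur
      nbr_order[[cur]] <<- c(nbr_order[[cur]], op$atom)
      ring_open[[key]] <<- NULL
    }
  }

  while (pos <= n) {
    ch <- chars[pos]
    if (ch == "(") {
      if (is.na(prev)) fail("branch with no preceding atom")
      stack <- c(stack, prev)
      pos <- pos + 1L
    } else if (ch == ")") {
      if (!length(stack)) fail("unbalanced ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- ch
      pos <- pos + 1L
    } else if (ch == "%") {
      if (pos + 2 > n) fail("truncated %nn ring number")
      num <- suppressWarnings(as.integer(paste0(chars[pos + 1], chars[pos + 2])))
      if (is.na(num)) fail("bad %nn ring number")
      if (is.na(prev)) fail("ring number before any atom")
      handle_ring(num, prev, pending_bond); pending_bond <- ""
      pos <- pos + 3L
    } else if (grepl("[0-9]", ch)) {
      if (is.na(prev)) fail("ring number before any atom")
      handle_ring(as.integer(ch), prev, pending_bond); pending_bond <- ""
      pos <- pos + 1L
    } else if (ch == "[") {
      rest <- substr(text, pos, n)
      m <- regmatches(rest, regexec(BRACKET_RE, rest))[[1]]
      if (!length(m)) fail("malformed bracket atom")
      sym <- m[3]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
      symbol <- if (aromatic) paste0(toupper(substr(sym, 1, 1)),
                                     substr(sym, 2, 10)) else sym
      stereo <- m[4]
      htok <- m[5]
      hcount <- if (htok == "") 0L else if (htok == "H") 1L else
        as.integer(substr(htok, 2, 10))
      ctok <- m[6]
      charge <- if (ctok == "") 0L
        else if (grepl("^\\++$", ctok)) nchar(ctok)
        else if (grepl("^-+$", ctok)) -nchar(ctok)
        else as.integer(ctok)
      map <- if (is.na(m[7]) || m[7] == "") 0L else as.integer(m[7])
      if (symbol == "H") {
        # explicit hydrogen atom: collapse onto the attaching heavy atom
        if (is.na(prev)) fail("leading explicit hydrogen is unsupported")
        atoms[[prev]]$hcount <- atoms[[prev]]$hcount + 1L
        pos <- pos + nchar(m[1])
        pending_bond <- ""
        next
      }
      cur <- add_atom(symbol, aromatic, as.integer(charge), hcount, map,
                      stereo, hexplicit = TRUE)
      if (stereo != "" && hcount == 1L) {
        # implicit-H neighbour slot: right after the preceding atom
        nbr_order[[cur]] <- if (is.na(prev)) 0L else integer(0)
      }
      if (!is.na(prev)) add_bond(prev, cur, pending_bond)
      if (stereo != "" && hcount == 1L && !is.na(prev)) {
        nbr_order[[cur]] <- c(nbr_order[[cur]], 0L)
      }
      pending_bond <- ""
      prev <- cur
      pos <- pos + nchar(m[1])
    } else if (grepl("[A-Za-z*]", ch)) {
      two <- if (pos < n) paste0(ch, chars[pos + 1]) else ch
      if (two %in% c("Cl", "Br")) { sym <- two; pos <- pos + 2L }
      else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        sym <- ch; pos <- pos + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        sym <- ch; pos <- pos + 1L
      } else fail("unknown atom symbol outside brackets")
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
      symbol <- if (aromatic) toupper(sym) else sym
      cur <- add_atom(symbol, aromatic, 0L, NA_integer_, 0L, "",
                      hexplicit = FALSE)
      if (!is.na(prev)) add_bond(prev, cur, pending_bond)
      pending_bond <- ""
      prev <- cur
    } else if (ch == ".") {
      fail("dot-separated components are reactions' job; parse_molecule takes one molecule")
    } else fail("unexpected character")
  }
  if (length(stack)) {
    pos <- n
    fail("unbalanced '(' (unclosed branch)")
  }
  if (length(ring_open)) {
    pos <- n
    fail(sprintf("unclosed ring bond number(s): %s",
                 paste(names(ring_open), collapse = ",")))
  }
  if (!length(atoms)) fail("no atoms")

  at <- data.frame(
    symbol = vapply(atoms, `[[`, "", "symbol"),
    aromatic = vapply(atoms, `[[`, TRUE, "aromatic"),
    charge = vapply(atoms, `[[`, 0L, "charge"),
    hcount = vapply(atoms, `[[`, 0L, "hcount"),
    map = vapply(atoms, `[[`, 0L, "map"),
    stereo = vapply(atoms, `[[`, "", "stereo"),
    hexplicit = vapply(atoms, `[[`, TRUE, "hexplicit"),
    stringsAsFactors = FALSE)
  new_molecule(at, bonds, chiral_order = nbr_order)
}

# implicit H for organic-subset atoms, aromaticity + E/Z perception
finish_molecule <- function(mol) {
  bov <- bond_order_value(mol$bonds)
  osum <- numeric(n_atoms(mol))
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      osum[mol$bonds$a1[k]] <- osum[mol$bonds$a1[k]] + bov[k]
      osum[mol$bonds$a2[k]] <- osum[mol$bonds$a2[k]] + bov[k]
    }
  }
  for (i in seq_len(n_atoms(mol))) {
    if (is.na(mol$atoms$hcount[i])) {
      s <- osum[i]
      if (mol$atoms$aromatic[i]) s <- max(s, 2 * 1.5)  # terminal aromatic never occurs
      mol$atoms$hcount[i] <- implicit_h_count(mol$atoms$symbol[i],
                                              mol$atoms$aromatic[i], s)
    }
  }
  mol$atoms$hexplicit <- NULL
  mol <- perceive_aromaticity(mol)
  mol <- perceive_ez(mol)
  mol
}

# Canonical serialisation ------------------------------------------------------

# Morgan-style canonical ranks: iterative refinement over
# (symbol, aromatic, charge, hcount, degree), ties broken deterministically.
# Refinement only ever splits classes, so it stops when the class count
# stabilises (comparing labels directly can oscillate between relabelings).
canonical_ranks <- function(mol, use_maps = FALSE) {
  n <- n_atoms(mol)
  adj <- adjacency_list(mol)
  refine <- function(rank) {
    repeat {
      key <- vapply(seq_len(n), function(i) {
        paste(sprintf("%05d", rank[i]),
              paste(sprintf("%05d", sort(rank[adj[[i]]])), collapse = ","),
              sep = ":")
      }, "")
      new_rank <- match(key, sort(unique(key)))
      if (length(unique(new_rank)) == length(unique(rank))) return(new_rank)
      rank <- new_rank
    }
  }
  inv <- paste(mol$atoms$symbol, mol$atoms$aromatic, mol$atoms$charge,
               mol$atoms$hcount, lengths(adj),
               if (use_maps) mol$atoms$map else 0L, sep = "|")
  rank <- refine(match(inv, sort(unique(inv))))
  # break remaining ties one at a time (lowest atom index in smallest class)
  while (length(unique(rank)) < n) {
    tab <- table(rank)
    tied <- as.integer(names(tab)[tab > 1])
    cls <- min(tied)
    i <- which(rank == cls)[1]
    rank <- rank * 2L
    rank[i] <- rank[i] - 1L
    rank <- refine(match(rank, sort(unique(rank))))
  }
  rank
}

needs_bracket <- function(mol, i, computed_h) {
  a <- mol$atoms[i, ]
  a$charge != 0 || a$map != 0 || a$stereo != "" ||
    !(a$symbol %in% ORGANIC_SUBSET) || a$hcount != computed_h
}

#' Serialize a molecule to SMILES
#'
#' Writes a canonical-order SMILES string preserving charges, aromaticity,
#' atom maps, tetrahedral parity and directional double-bond tokens, such
#' that `parse_molecule(serialize_molecule(m))` reproduces the molecular
#' graph.
#'
#' @param mol an `rs_mol`.
#' @return a SMILES string.
#' @export
serialize_molecule <- function(mol) {
  n <- n_atoms(mol)
  adj <- adjacency_list(mol)
  bmap <- bond_index_map(mol)
  rank <- canonical_ranks(mol)
  start <- which.min(rank)

  visited <- logical(n)
  ring_counter <- 0L
  ring_digit <- list()      # "i-j" -> digit
  atom_ring_digits <- rep(list(character(0)), n)
  atom_emit_nbrs <- rep(list(integer()), n)

  # pass 1: DFS to discover tree/ring edges and emission order
  tree_child <- rep(list(integer()), n)
  parent <- rep(NA_integer_, n)
  order_seen <- integer(0)
  dfs1 <- function(v) {
    visited[v] <<- TRUE
    order_seen <<- c(order_seen, v)
    nbrs <- adj[[v]][order(rank[adj[[v]]])]
    for (w in nbrs) {
      if (!is.na(parent[v]) && w == parent[v]) next
      key <- paste(min(v, w), max(v, w), sep = "-")
      if (visited[w]) {
        if (is.null(ring_digit[[key]])) {
          ring_counter <<- ring_counter + 1L
          ring_digit[[key]] <<- ring_counter
          atom_ring_digits[[w]] <<- c(atom_ring_digits[[w]], key)
          atom_ring_digits[[v]] <<- c(atom_ring_digits[[v]], key)
        }
      } else {
        parent[w] <<- v
        tree_child[[v]] <<- c(tree_child[[v]], w)
        dfs1(w)
      }
    }
  }
  dfs1(start)
  if (!all(visited))
    rs_error("cannot serialize a disconnected molecule", "rs_format_error")

  bond_token <- function(i, j) {
    k <- bmap[[paste(min(i, j), max(i, j), sep = "-")]]
    b <- mol$bonds[k, ]
    if (b$updown != "") {
      # directional token is stored as written a1 -> a2
      if (b$a1 == i) b$updown else (if (b$updown == "/") "\\" else "/")
    } else if (b$aromatic) {
      if (mol$atoms$aromatic[i] && mol$atoms$aromatic[j]) "" else ":"
    } else if (b$order == 2) "="
    else if (b$order == 3) "#"
    else ""
  }

  # pass 2: emit, tracking neighbour order at each atom for parity fix-up
  emit_atom <- function(i) {
    a <- mol$atoms[i, ]
    ch <- if (a$aromatic) tolower(a$symbol) else a$symbol
    computed_h <- {
      osum <- 0
      for (w in adj[[i]]) {
        k <- bmap[[paste(min(i, w), max(i, w), sep = "-")]]
        osum <- osum + (if (mol$bonds$aromatic[k]) 1.5 else mol$bonds$order[k])
      }
      implicit_h_count(a$symbol, a$aromatic, osum)
    }
    if (!needs_bracket(mol, i, computed_h)) return(ch)
    stereo_tok <- a$stereo
    if (stereo_tok != "") {
      # adjust parity for the difference between the stored reference
      # neighbour order and the order in which neighbours are emitted
      stored <- mol$chiral_order[[i]]
      emitted <- atom_emit_nbrs[[i]]
      if (a$hcount == 1L && !(0L %in% emitted)) {
        # implicit H is written right after the atom symbol: its emission
        # slot is after the parent (slot 1) if a parent exists, else slot 0
        pos <- if (is.na(parent[i])) 1L else 2L
        emitted <- append(emitted, 0L, after = pos - 1L)
      }
      if (length(stored) == length(emitted) && length(stored) >= 3 &&
          setequal(stored, emitted)) {
        perm <- match(emitted, stored)
        if (permutation_parity(perm) == -1L)
          stereo_tok <- if (stereo_tok == "@") "@@" else "@"
      }
    }
    paste0("[", ch, stereo_tok,
           if (a$hcount == 1) "H" else if (a$hcount > 1) paste0("H", a$hcount) else "",
           if (a$charge > 0) paste0("+", if (a$charge > 1) a$charge else ""),
           if (a$charge < 0) paste0("-", if (a$charge < -1) -a$charge else ""),
           if (a$map > 0) paste0(":", a$map) else "", "]")
  }

  # precompute emission neighbour order (parent, ring closures, children)
  for (v in order_seen) {
    nb <- integer(0)
    if (!is.na(parent[v])) nb <- parent[v]
    for (key in atom_ring_digits[[v]]) {
      ij <- as.integer(strsplit(key, "-")[[1]])
      nb <- c(nb, setdiff(ij, v))
    }
    nb <- c(nb, tree_child[[v]])
    atom_emit_nbrs[[v]] <- nb
  }

  build <- function(v) {
    out <- emit_atom(v)
    for (key in atom_ring_digits[[v]]) {
      d <- ring_digit[[key]]
      ij <- as.integer(strsplit(key, "-")[[1]])
      w <- setdiff(ij, v)
      tok <- bond_token(v, w)
      dstr <- if (d > 9) paste0("%", sprintf("%02d", d)) else as.character(d)
      out <- paste0(out, tok, dstr)
    }
    kids <- tree_child[[v]]
    if (length(kids)) {
      for (q in seq_along(kids)) {
        w <- kids[q]
        frag <- paste0(bond_token(v, w), build(w))
        out <- if (q < length(kids)) paste0(out, "(", frag, ")")
               else paste0(out, frag)
      }
    }
    out
  }
  build(start)
}

permutation_parity <- function(perm) {
  n <- length(perm)
  visited <- logical(n)
  sign <- 1L
  for (i in seq_len(n)) {
    if (visited[i]) next
    len <- 0L; j <- i
    while (!visited[j]) { visited[j] <- TRUE; j <- perm[j]; len <- len + 1L }
    if (len %% 2L == 0L) sign <- -sign
  }
  sign
}
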