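# Molecule container: an attributed molecular graph over heavy atoms.
#
# atoms: symbol, aromatic, charge, hcount (implicit H), map (0 = unmapped),
#        stereo ("" / "@" / "@@", local parity w.r.t. chiral_order)
# bonds: a1, a2 (atom indices), order (1, 2, 3), aromatic, updown (directional
#        single-bond token as written a1 -> a2), stereo ("" / "E" / "Z")
# chiral_order: per-atom neighbour index list fixing the reference frame of
#        the stereo token; 0 stands for the implicit hydrogen.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                     F = 1, Cl = 1, Br = 1, I = 1)

new_molecule <- function(atoms, bonds, chiral_order = NULL, smiles = NA_character_) {
  if (is.null(chiral_order)) chiral_order <- rep(list(integer()), nrow(atoms))
  structure(list(atoms = atoms, bonds = bonds,
                 chiral_order = chiral_order, smiles = smiles),
            class = "rs_mol")
}

#' @export
print.rs_mol <- function(x, ...) {
  cat(sprintf("<rs_mol> %d atoms, %d bonds: %s\n",
              n_atoms(x), nrow(x$bonds),
              if (is.na(x$smiles)) serialize_molecule(x) else x$smiles))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

# Numeric bond order with aromatic bonds counted as 1.5.
bond_order_value <- function(bonds) ifelse(bonds$aromatic, 1.5, bonds$order)

empty_bonds <- function() {
  data.frame(a1 = integer(), a2 = integer(), order = numeric(),
             aromatic = logical(), updown = character(),
             stereo = character(), stringsAsFactors = FALSE)
}

# Neighbour list (adjacency) --------------------------------------------------

adjacency_list <- function(mol) {
  adj <- rep(list(integer()), n_atoms(mol))
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

# bond index lookup keyed "i-j" with i < j
bond_index_map <- function(mol) {
  if (!nrow(mol$bonds)) return(character(0))
  key <- paste(pmin(mol$bonds$a1, mol$bonds$a2),
               pmax(mol$bonds$a1, mol$bonds$a2), sep = "-")
  stats::setNames(seq_along(key), key)
}

is_connected_graph <- function(n, bonds) {
  if (n <= 1) return(TRUE)
  adj <- rep(list(integer()), n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$a1[k]; j <- bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n); queue <- 1L; seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

# Implicit hydrogens ----------------------------------------------------------

# Organic-subset atoms written without brackets get implicit H from the
# default valence; aromatic bonds contribute 1.5 to the bond-order sum.
implicit_h_count <- function(symbol, aromatic, order_sum) {
  val <- DEFAULT_VALENCE[[symbol]]
  if (is.null(val)) return(0L)
  h <- val - ceiling(order_sum - 1e-9)
  max(0L, as.integer(h))
}

# Ring perception -------------------------------------------------------------

# An edge is a ring edge iff its endpoints stay connected after removing it.
ring_edges <- function(mol) {
  nb <- nrow(mol$bonds)
  if (!nb) return(logical(0))
  out <- logical(nb)
  for (k in seq_len(nb)) {
    keep <- mol$bonds[-k, , drop = FALSE]
    i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
    adj <- rep(list(integer()), n_atoms(mol))
    for (q in seq_len(nrow(keep))) {
      a <- keep$a1[q]; b <- keep$a2[q]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    seen <- logical(n_atoms(mol)); queue <- i; seen[i] <- TRUE
    while (length(queue) && !seen[j]) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    out[k] <- seen[j]
  }
  out
}

ring_atom_flags <- function(mol) {
  re <- ring_edges(mol)
  flags <- logical(n_atoms(mol))
  if (any(re)) {
    flags[unique(c(mol$bonds$a1[re], mol$bonds$a2[re]))] <- TRUE
  }
  flags
}

# Smallest ring size through each ring edge (BFS avoiding the edge itself);
# returns the set of ring sizes present and the cyclomatic ring count.
ring_info <- function(mol) {
  re <- ring_edges(mol)
  sizes <- integer(0)
  if (any(re)) {
    adj <- adjacency_list(mol)
    for (k in which(re)) {
      i <- mol$bonds$a1[k]; j <- mol$bonds$a2[k]
      # BFS from i to j not using edge k
      dist <- rep(NA_integer_, n_atoms(mol)); dist[i] <- 0L; queue <- i
      while (length(queue) && is.na(dist[j])) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) {
          if ((v == i && w == j) || (v == j && w == i)) next
          if (is.na(dist[w])) { dist[w] <- dist[v] + 1L; queue <- c(queue, w) }
        }
      }
      if (!is.na(dist[j])) sizes <- c(sizes, dist[j] + 1L)
    }
  }
  n_rings <- if (nrow(mol$bonds)) nrow(mol$bonds) - n_atoms(mol) +
    1L else 0L  # connected molecule: cyclomatic number
  list(sizes = sort(unique(sizes)), n_rings = max(0L, n_rings),
       edge_ring = re, edge_ring_size = {
         s <- rep(NA_integer_, nrow(mol$bonds))
         if (any(re)) s[which(re)] <- sizes
         s
       })
}

# Smallest-ring-size per atom (NA if acyclic atom)
atom_ring_sizes <- function(mol) {
  ri <- ring_info(mol)
  out <- rep(list(integer()), n_atoms(mol))
  if (any(ri$edge_ring)) {
    for (k in which(ri$edge_ring)) {
      sz <- ri$edge_ring_size[k]
      for (a in c(mol$bonds$a1[k], mol$bonds$a2[k]))
        out[[a]] <- sort(unique(c(out[[a]], sz)))
    }
  }
  out
}

# Aromaticity perception ------------------------------------------------------

# Single stated model, applied once at parse time: atoms written lowercase are
# aromatic, and in addition any six-membered all-carbon ring whose bonds
# alternate single/double (a Kekule benzene) is aromatised.  This keeps path
# and environment labels identical for the two common ways of writing benzene.
perceive_aromaticity <- function(mol) {
  ri <- ring_info(mol)
  if (!any(ri$edge_ring)) return(mol)
  adj <- adjacency_list(mol)
  bmap <- bond_index_map(mol)
  # find 6-cycles by walking ring edges
  n <- n_atoms(mol)
  seen_cycles <- character(0)
  find6 <- function(start) {
    res <- list()
    path <- start
    walk <- function(v, depth) {
      if (depth == 6) {
        if (start %in% adj[[v]]) res[[length(res) + 1]] <<- path
        return()
      }
      for (w in adj[[v]]) {
        if (w %in% path) next
        path <<- c(path, w); walk(w, depth + 1); path <<- path[-length(path)]
      }
    }
    walk(start, 1)
    res
  }
  for (start in seq_len(n)) {
    for (cyc in find6(start)) {
      key <- paste(sort(cyc), collapse = ",")
      if (key %in% seen_cycles) next
      seen_cycles <- c(seen_cycles, key)
      if (!all(mol$atoms$symbol[cyc] == "C")) next
      if (any(mol$atoms$aromatic[cyc])) next
      eidx <- integer(6)
      ok <- TRUE
      for (q in 1:6) {
        a <- cyc[q]; b <- cyc[if (q == 6) 1 else q + 1]
        k <- bmap[[paste(min(a, b), max(a, b), sep = "-")]]
        if (is.null(k)) { ok <- FALSE; break }
        eidx[q] <- k
      }
      if (!ok) next
      ords <- mol$bonds$order[eidx]
      if (all(ords[c(1, 3, 5)] == 1) && all(ords[c(2, 4, 6)] == 2) ||
          all(ords[c(1, 3, 5)] == 2) && all(ords[c(2, 4, 6)] == 1)) {
        mol$atoms$aromatic[cyc] <- TRUE
        mol$bonds$order[eidx] <- 1
        mol$bonds$aromatic[eidx] <- TRUE
      }
    }
  }
  mol
}

# E/Z perception from directional bonds ---------------------------------------

# F/C=C/F is trans (E); F/C=C\F is cis (Z).  Directional tokens are stored as
# written a1 -> a2; only the common linear notation is interpreted.
perceive_ez <- function(mol) {
  bonds <- mol$bonds
  dbl <- which(bonds$order == 2 & !bonds$aromatic)
  for (k in dbl) {
    i <- bonds$a1[k]; j <- bonds$a2[k]
    d1 <- NA_real_; d2 <- NA_real_
    for (q in seq_len(nrow(bonds))) {
      if (q == k || bonds$updown[q] == "") next
      sgn <- if (bonds$updown[q] == "/") 1 else -1
      if (bonds$a2[q] == i || bonds$a1[q] == i) {
        # substituent side of atom i: token written x->i keeps sign,
        # i->x flips it
        d1 <- if (bonds$a2[q] == i) sgn else -sgn
      } else if (bonds$a1[q] == j || bonds$a2[q] == j) {
        # token written j->y keeps sign, y->j flips it
        d2 <- if (bonds$a1[q] == j) sgn else -sgn
      }
    }
    if (!is.na(d1) && !is.na(d2)) {
      mol$bonds$stereo[k] <- if (d1 == d2) "E" else "Z"
    }
  }
  mol
}

# Validation -------------------------------------------------------------------

validate_molecule <- function(mol, require_connected = TRUE) {
  at <- mol$atoms; bd <- mol$bonds
  if (!nrow(at)) rs_error("molecule has no atoms", "rs_format_error")
  if (nrow(bd)) {
    if (any(bd$a1 < 1 | bd$a1 > nrow(at) | bd$a2 < 1 | bd$a2 > nrow(at)))
      rs_error("bond endpoint out of range", "rs_format_error")
  }
  maps <- at$map[at$map > 0]
  if (anyDuplicated(maps))
    rs_error("duplicate nonzero atom-map number within one molecule",
             "rs_mapping_error")
  if (require_connected && !is_connected_graph(nrow(at), bd))
    rs_error("molecule graph is not connected (use parse_reaction for multi-component input)",
             "rs_format_error")
  invisible(mol)
}
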