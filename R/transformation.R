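# Transformation-level similarity: find the reaction center from the
# atom-atom mapping (bonds formed, broken or changing order, plus mapped
# heavy atoms whose implicit hydrogen count changes), expand it to bond
# distance k on each side, extract the induced fragments, and score the
# fragment sets with the whole-reaction procedure.

# map-keyed bond table of one reaction side: key "m1<m2", value order (1.5
# for aromatic); only bonds between two mapped atoms are representable
side_bond_table <- function(mols) {
  keys <- character(0); vals <- numeric(0)
  for (m in mols) {
    if (!nrow(m$bonds)) next
    for (q in seq_len(nrow(m$bonds))) {
      m1 <- m$atoms$map[m$bonds$a1[q]]; m2 <- m$atoms$map[m$bonds$a2[q]]
      if (m1 == 0 || m2 == 0) next
      keys <- c(keys, paste(min(m1, m2), max(m1, m2), sep = "<"))
      vals <- c(vals, if (m$bonds$aromatic[q]) 1.5 else m$bonds$order[q])
    }
  }
  stats::setNames(vals, keys)
}

side_h_table <- function(mols) {
  maps <- integer(0); hs <- integer(0)
  for (m in mols) {
    sel <- m$atoms$map > 0
    maps <- c(maps, m$atoms$map[sel]); hs <- c(hs, m$atoms$hcount[sel])
  }
  stats::setNames(hs, maps)
}

#' Find the reaction center of a mapped reaction
#'
#' An atom belongs to the center iff it is an endpoint of a bond present on
#' only one side of the reaction, or of a bond whose order differs between
#' the sides, or iff its implicit hydrogen count changes (proton transfers
#' leave the heavy-atom bond set unchanged).  Stereo-only changes do not
#' create center atoms.
#'
#' @param rxn a mapped `rs_reaction`.
#' @return sorted integer vector of atom-map numbers (empty for an identity
#'   reaction).
#' @export
find_reaction_center <- function(rxn) {
  if (!rxn$mapped)
    rs_error("reaction is not fully atom-mapped; supply atom maps (automatic mapping is not performed)",
             "rs_mapping_error")
  sb <- side_bond_table(rxn$substrates)
  pb <- side_bond_table(rxn$products)
  changed_keys <- union(
    setdiff(names(sb), names(pb)),
    setdiff(names(pb), names(sb)))
  common <- intersect(names(sb), names(pb))
  changed_keys <- c(changed_keys, common[sb[common] != pb[common]])
  center <- unique(unlist(lapply(strsplit(changed_keys, "<", fixed = TRUE),
                                 as.integer)))
  sh <- side_h_table(rxn$substrates)
  ph <- side_h_table(rxn$products)
  hmaps <- names(sh)[sh[names(sh)] != ph[names(sh)]]
  sort(unique(c(center, as.integer(hmaps))))
}

# induced-subgraph fragment extraction from one molecule; returns a list of
# connected fragments (possibly empty)
induced_fragments <- function(mol, keep_idx) {
  if (!length(keep_idx)) return(list())
  keep_idx <- sort(keep_idx)
  remap <- match(seq_len(n_atoms(mol)), keep_idx)
  atoms <- mol$atoms[keep_idx, , drop = FALSE]
  rownames(atoms) <- NULL
  keep_bond <- mol$bonds$a1 %in% keep_idx & mol$bonds$a2 %in% keep_idx
  bonds <- mol$bonds[keep_bond, , drop = FALSE]
  # complete valences at cut bonds with implicit hydrogens
  cut <- mol$bonds[!keep_bond, , drop = FALSE]
  if (nrow(cut)) {
    for (q in seq_len(nrow(cut))) {
      ov <- if (cut$aromatic[q]) 1L else as.integer(cut$order[q])
      for (endp in c(cut$a1[q], cut$a2[q])) {
        if (endp %in% keep_idx)
          atoms$hcount[remap[endp]] <- atoms$hcount[remap[endp]] + ov
      }
    }
  }
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  rownames(bonds) <- NULL
  # stereo frames referencing removed neighbours are dropped
  chiral <- lapply(seq_along(keep_idx), function(ii) {
    old <- mol$chiral_order[[keep_idx[ii]]]
    if (!length(old)) return(integer())
    new <- ifelse(old == 0L, 0L, remap[pmax(old, 1L)])
    if (anyNA(new)) integer() else as.integer(new)
  })
  for (ii in seq_along(keep_idx)) {
    if (atoms$stereo[ii] != "" && !length(chiral[[ii]])) atoms$stereo[ii] <- ""
  }
  frag <- new_molecule(atoms, bonds, chiral_order = chiral)
  # split connected components
  n <- nrow(atoms)
  comp <- rep(0L, n); nc <- 0L
  adj <- adjacency_list(frag)
  for (s in seq_len(n)) {
    if (comp[s]) next
    nc <- nc + 1L; queue <- s; comp[s] <- nc
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!comp[w]) { comp[w] <- nc; queue <- c(queue, w) }
    }
  }
  lapply(seq_len(nc), function(ci) {
    idx <- which(comp == ci)
    sub_remap <- match(seq_len(n), idx)
    a2 <- atoms[idx, , drop = FALSE]; rownames(a2) <- NULL
    kb <- bonds$a1 %in% idx & bonds$a2 %in% idx
    b2 <- bonds[kb, , drop = FALSE]
    b2$a1 <- sub_remap[b2$a1]; b2$a2 <- sub_remap[b2$a2]
    rownames(b2) <- NULL
    ch2 <- lapply(idx, function(ii) {
      old <- chiral[[ii]]
      if (!length(old)) return(integer())
      new <- ifelse(old == 0L, 0L, sub_remap[pmax(old, 1L)])
      if (anyNA(new)) integer() else as.integer(new)
    })
    m <- new_molecule(a2, b2, chiral_order = ch2)
    m$smiles <- serialize_molecule(m)
    m
  })
}

#' Extract the transformation region at degree k
#'
#' Breadth-first expansion from the center atoms over bonds, independently on
#' each side; induced subgraphs keep elements, charges, bond orders and any
#' stereo whose reference atoms survive; each connected component becomes one
#' fragment molecule whose cut-bond valences are filled with implicit
#' hydrogens.
#'
#' @param rxn a mapped `rs_reaction`.
#' @param k transformation degree (bond-distance radius), default 1.
#' @return list with `k`, `center_atoms` (map numbers),
#'   `substrate_fragments`, `product_fragments`.
#' @export
extract_transformation_region <- function(rxn, k = 1L) {
  if (k < 0) rs_error("transformation degree k must be >= 0", "rs_config_error")
  center <- find_reaction_center(rxn)
  if (!length(center)) {
    rs_warn("empty reaction center (identity reaction): empty transformation region")
    return(list(k = as.integer(k), center_atoms = integer(0),
                substrate_fragments = list(), product_fragments = list()))
  }
  expand_side <- function(mols) {
    out <- list()
    for (m in mols) {
      seed <- which(m$atoms$map %in% center)
      if (!length(seed)) next
      adj <- adjacency_list(m)
      dist <- rep(NA_integer_, n_atoms(m))
      dist[seed] <- 0L
      queue <- seed
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (dist[v] >= k) next
        for (w in adj[[v]]) if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L; queue <- c(queue, w)
        }
      }
      out <- c(out, induced_fragments(m, which(!is.na(dist))))
    }
    out
  }
  list(k = as.integer(k), center_atoms = center,
       substrate_fragments = expand_side(rxn$substrates),
       product_fragments = expand_side(rxn$products))
}

#' Transformation-level similarity
#'
#' Extracts the degree-`k` transformation regions of both reactions and
#' scores the substrate and product fragment sets with the whole-reaction
#' pairing procedure.  A reaction with an empty center (identity reaction)
#' scores 0 against anything at this level.
#'
#' @param rxnA,rxnB mapped `rs_reaction` objects.
#' @param k transformation degree.
#' @param fp_type fingerprint type.
#' @param measure similarity measure.
#' @param detail return pairing traces alongside the score.
#' @return score in `[0, 1]`, or a detail list as in [reaction_similarity()].
#' @export
transformation_similarity <- function(rxnA, rxnB, k = 1L,
                                      fp_type = "extended",
                                      measure = "tanimoto",
                                      detail = FALSE) {
  regA <- extract_transformation_region(rxnA, k)
  regB <- extract_transformation_region(rxnB, k)
  nfrag <- function(r) length(r$substrate_fragments) + length(r$product_fragments)
  if (!nfrag(regA) || !nfrag(regB)) {
    res <- list(score = 0, substrate_pairing = NULL, product_pairing = NULL)
    return(if (detail) res else res$score)
  }
  ps <- pair_side(regA$substrate_fragments, regB$substrate_fragments,
                  fp_type, measure)
  pp <- pair_side(regA$product_fragments, regB$product_fragments,
                  fp_type, measure)
  scores <- c(ps$pairs$score, pp$pairs$score)
  res <- list(score = if (length(scores)) mean(scores) else 0,
              substrate_pairing = ps, product_pairing = pp,
              region_A = regA, region_B = regB)
  if (detail) res else res$score
}
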