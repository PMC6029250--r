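# Physicochemical layer: molecular mass, additive van der Waals volume,
# rule-based protonation at a given pH, and the Jaccard-distance property
# correction Rs = Rf / (1 + Jdist) of the fingerprint score.

# standard atomic weights (IUPAC 2021, conventional values), Da
ATOMIC_WEIGHTS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                    F = 18.998, Na = 22.990, Mg = 24.305, P = 30.974,
                    S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078,
                    Fe = 55.845, Zn = 65.38, Se = 78.971, Br = 79.904,
                    I = 126.904)

# atomic van der Waals volume contributions (A^3) for the additive VABC
# scheme: V = sum(atom contributions) - 5.92 * N_bonds - 14.7 * R_aromatic
# - 3.8 * R_nonaromatic, bonds and atoms counted with hydrogens
VDW_VOLUME <- c(H = 7.24, B = 40.48, C = 20.58, N = 15.60, O = 14.71,
                F = 13.31, Na = 49.00, Mg = 21.69, P = 24.43, S = 24.43,
                Cl = 22.45, K = 87.11, Ca = 38.79, Fe = 41.05, Zn = 27.39,
                Se = 28.73, Br = 26.52, I = 32.52)

#' Molecular mass
#'
#' Sum of standard atomic weights over heavy atoms and implicit hydrogens.
#'
#' @param mol an `rs_mol`.
#' @return mass in Da.
#' @export
molecular_mass <- function(mol) {
  sym <- mol$atoms$symbol
  unknown <- setdiff(sym, names(ATOMIC_WEIGHTS))
  if (length(unknown))
    rs_error(sprintf("no atomic weight for element(s): %s",
                     paste(unknown, collapse = ", ")), "rs_element_error")
  sum(ATOMIC_WEIGHTS[sym]) + sum(mol$atoms$hcount) * ATOMIC_WEIGHTS[["H"]]
}

#' Molecular van der Waals volume (additive)
#'
#' Atom-contribution volume in the VABC style: the sum of atomic van der
#' Waals volumes (hydrogens included) minus 5.92 per bond (hydrogen bonds
#' included) minus 14.7 per aromatic ring and 3.8 per non-aromatic ring.
#' Benzene evaluates to about 81.2 A^3 and cyclohexane to about 99.9 A^3
#' under these parameters.
#'
#' @param mol an `rs_mol`.
#' @return volume in cubic Angstrom.
#' @export
molecular_volume <- function(mol) {
  sym <- mol$atoms$symbol
  unknown <- setdiff(sym, names(VDW_VOLUME))
  if (length(unknown))
    rs_error(sprintf("no volume parameter for element(s): %s",
                     paste(unknown, collapse = ", ")), "rs_element_error")
  nH <- sum(mol$atoms$hcount)
  atom_sum <- sum(VDW_VOLUME[sym]) + nH * VDW_VOLUME[["H"]]
  n_bonds <- nrow(mol$bonds) + nH
  ri <- ring_info(mol)
  n_arom <- 0L; n_plain <- 0L
  if (ri$n_rings > 0) {
    # classify the cyclomatic rings by the aromaticity of their ring bonds:
    # count aromatic ring systems through aromatic ring sizes present
    arom_ring_edges <- ri$edge_ring & mol$bonds$aromatic
    # ring count split proportional to edge classes is ill-posed in fused
    # systems; count a ring aromatic when all its smallest-ring edges are
    n_arom <- if (any(arom_ring_edges)) {
      # number of independent cycles within the aromatic-bond subgraph
      sub <- mol$bonds[arom_ring_edges, , drop = FALSE]
      verts <- unique(c(sub$a1, sub$a2))
      comps <- count_components(verts, sub)
      nrow(sub) - length(verts) + comps
    } else 0L
    n_plain <- ri$n_rings - n_arom
  }
  atom_sum - 5.92 * n_bonds - 14.7 * n_arom - 3.8 * max(0L, n_plain)
}

count_components <- function(verts, bonds) {
  if (!length(verts)) return(0L)
  idx <- stats::setNames(seq_along(verts), verts)
  adj <- rep(list(integer()), length(verts))
  for (q in seq_len(nrow(bonds))) {
    i <- idx[[as.character(bonds$a1[q])]]; j <- idx[[as.character(bonds$a2[q])]]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(length(verts)); nc <- 0L
  for (s in seq_along(verts)) {
    if (seen[s]) next
    nc <- nc + 1L; queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  nc
}

# pKa rule table ---------------------------------------------------------------

#' Load the bundled ionizable-group pKa rules
#'
#' Each rule is a SMARTS pattern (first pattern atom = the ionizable atom),
#' a representative pKa and an acid/base flag.  The bundled table covers the
#' common biochemical ionizable groups; a user TSV (columns smarts, pka,
#' type) can be supplied instead.
#'
#' @param path optional path to an alternative rule TSV.
#' @return data.frame with columns `name`, `smarts`, `pka`, `type`.
#' @export
pka_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pka_rules.tsv", package = "reactsim")
    if (!nzchar(path)) path <- file.path("inst", "extdata", "pka_rules.tsv")
  }
  if (!file.exists(path))
    rs_error(sprintf("pKa rule table not found: %s", path), "rs_config_error")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  if (!all(c("name", "smarts", "pka", "type") %in% names(df)))
    rs_error("pKa rule table needs columns name, smarts, pka, type",
             "rs_config_error")
  df
}

#' Assign majority protonation states at a given pH
#'
#' Each ionizable group matched by the rule table is set to its majority
#' state under the Henderson-Hasselbalch rule: an acid group is deprotonated
#' (charge -1, one H removed at the matched atom) iff `pH > pKa`; a base
#' group is protonated (+1, one H added) iff `pH < pKa`.  Rules only match
#' neutral groups, so the operation is idempotent at a fixed pH.  Multiple
#' groups on one molecule are handled independently.
#'
#' @param mol an `rs_mol`.
#' @param pH pH value in `[0, 14]`, default 7.
#' @param rules optional alternative rule table (see [pka_rules()]).
#' @return the molecule with updated formal charges and H counts.
#' @export
assign_charges_at_pH <- function(mol, pH = 7, rules = NULL) {
  if (pH < 0 || pH > 14)
    rs_error("pH must be within [0, 14]", "rs_config_error")
  rules <- rules %||% pka_rules()
  changed <- FALSE
  ctx <- smarts_context(mol)
  for (r in seq_len(nrow(rules))) {
    fire <- if (rules$type[r] == "acid") pH > rules$pka[r] else pH < rules$pka[r]
    if (!fire) next
    hits <- smarts_match_ctx(ctx, rules$smarts[r], all = TRUE)
    if (!length(hits)) next
    atoms_hit <- unique(vapply(hits, `[`, 1L, 1))
    for (i in atoms_hit) {
      if (rules$type[r] == "acid") {
        if (mol$atoms$hcount[i] < 1) next
        mol$atoms$charge[i] <- mol$atoms$charge[i] - 1L
        mol$atoms$hcount[i] <- mol$atoms$hcount[i] - 1L
      } else {
        mol$atoms$charge[i] <- mol$atoms$charge[i] + 1L
        mol$atoms$hcount[i] <- mol$atoms$hcount[i] + 1L
      }
      changed <- TRUE
    }
  }
  if (changed) mol$smiles <- serialize_molecule(mol)
  mol
}

# Jaccard property correction ---------------------------------------------------

#' Generalized Jaccard similarity of one property pair
#'
#' @param a,b positive property values (mass or volume) of the two molecules
#'   of one equivalent pair.
#' @return `min(a, b) / max(a, b)`, in `(0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  if (any(c(a, b) <= 0))
    rs_error("property values must be positive", "rs_validation_error")
  min(a, b) / max(a, b)
}

#' Average Jaccard distance over equivalent pairs
#'
#' Per property p, `Jdist_p = 1 - mean(Js)` over the N pairs; when both mass
#' and volume are selected the two per-property distances are averaged.
#'
#' @param pair_values a list, one element per selected property, each a
#'   two-column matrix (or data.frame) of positive paired property values.
#' @return Jdist in `[0, 1)`.
#' @export
jaccard_distance <- function(pair_values) {
  if (!length(pair_values))
    rs_error("no properties selected", "rs_config_error")
  per_prop <- vapply(pair_values, function(pv) {
    pv <- as.matrix(pv)
    if (!nrow(pv))
      rs_error("no equivalent pairs: property correction undefined (use Rs = Rf)",
               "rs_correction_error")
    js <- vapply(seq_len(nrow(pv)), function(q) jaccard_similarity(pv[q, 1], pv[q, 2]),
                 numeric(1))
    1 - mean(js)
  }, numeric(1))
  mean(per_prop)
}

#' Property-corrected similarity score
#'
#' @param Rf fingerprint-based reaction similarity, in `[0, 1]`.
#' @param Jdist average Jaccard property distance, in `[0, 1]`.
#' @return `Rs = Rf / (1 + Jdist)`, so `Rf/2 <= Rs <= Rf`.
#' @export
corrected_similarity <- function(Rf, Jdist) {
  if (Rf < 0 || Rf > 1 || Jdist < 0 || Jdist > 1)
    rs_error("Rf and Jdist must be in [0, 1]", "rs_validation_error")
  Rf / (1 + Jdist)
}

# End-to-end corrected reaction similarity --------------------------------------

#' Reaction similarity with physicochemical correction
#'
#' Computes the fingerprint score Rf at the requested level, then corrects it
#' with the Jaccard distance of the selected molecular properties evaluated
#' over the same greedy pairing used for Rf (pairs are not re-formed per
#' property).  With no formable pairs the correction is skipped (Rs = Rf).
#'
#' @param rxnA,rxnB `rs_reaction` objects.
#' @param level `"reaction"` or `"transformation"`.
#' @param k transformation degree (transformation level only).
#' @param fp_type,measure fingerprint type and similarity measure.
#' @param properties subset of `c("mass", "volume")`; empty means no
#'   correction.
#' @param pH when non-`NULL`, protonation states are assigned at this pH
#'   before fingerprinting (most useful with `fp_type = "enhanced"`).
#' @param orientation passed to [reaction_similarity()] (reaction level).
#' @return list with `Rf`, `Jdist`, `Rs`, `N` (number of equivalent pairs)
#'   and `properties_used`.
#' @export
corrected_reaction_similarity <- function(rxnA, rxnB,
                                          level = c("reaction", "transformation"),
                                          k = 1L, fp_type = "extended",
                                          measure = "tanimoto",
                                          properties = c("mass", "volume"),
                                          pH = NULL,
                                          orientation = "forward") {
  level <- match.arg(level)
  properties <- intersect(properties, c("mass", "volume"))
  if (!is.null(pH)) {
    adjust <- function(rxn) {
      rxn$substrates <- lapply(rxn$substrates, assign_charges_at_pH, pH = pH)
      rxn$products <- lapply(rxn$products, assign_charges_at_pH, pH = pH)
      rxn
    }
    rxnA <- adjust(rxnA); rxnB <- adjust(rxnB)
  }
  if (level == "reaction") {
    det <- reaction_similarity(rxnA, rxnB, fp_type, measure,
                               orientation = orientation, detail = TRUE)
    molsA_s <- rxnA$substrates; molsA_p <- rxnA$products
    if (identical(det$orientation, "reversed")) {
      molsB_s <- rxnB$products; molsB_p <- rxnB$substrates
    } else {
      molsB_s <- rxnB$substrates; molsB_p <- rxnB$products
    }
  } else {
    det <- transformation_similarity(rxnA, rxnB, k, fp_type, measure,
                                     detail = TRUE)
    if (is.null(det$substrate_pairing)) {
      return(list(Rf = 0, Jdist = NA_real_, Rs = 0, N = 0L,
                  properties_used = properties))
    }
    molsA_s <- det$region_A$substrate_fragments
    molsA_p <- det$region_A$product_fragments
    molsB_s <- det$region_B$substrate_fragments
    molsB_p <- det$region_B$product_fragments
  }
  Rf <- det$score
  pair_mols <- rbind(
    if (!is.null(det$substrate_pairing))
      cbind(det$substrate_pairing$pairs[, c("i", "j"), drop = FALSE], side = "s"),
    if (!is.null(det$product_pairing))
      cbind(det$product_pairing$pairs[, c("i", "j"), drop = FALSE], side = "p"))
  N <- if (is.null(pair_mols)) 0L else nrow(pair_mols)
  if (!length(properties) || N == 0) {
    if (N == 0) rs_warn("no equivalent pairs: property correction skipped")
    return(list(Rf = Rf, Jdist = if (length(properties)) 0 else NA_real_,
                Rs = Rf, N = as.integer(N), properties_used = properties))
  }
  prop_fun <- list(mass = molecular_mass, volume = molecular_volume)
  pv <- lapply(properties, function(p) {
    f <- prop_fun[[p]]
    t(vapply(seq_len(N), function(q) {
      i <- pair_mols$i[q]; j <- pair_mols$j[q]
      if (pair_mols$side[q] == "s") c(f(molsA_s[[i]]), f(molsB_s[[j]]))
      else c(f(molsA_p[[i]]), f(molsB_p[[j]]))
    }, numeric(2)))
  })
  Jdist <- jaccard_distance(pv)
  list(Rf = Rf, Jdist = Jdist, Rs = corrected_similarity(Rf, Jdist),
       N = as.integer(N), properties_used = properties)
}
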