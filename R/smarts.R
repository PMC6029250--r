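# A SMARTS-subset pattern matcher (subgraph isomorphism with atom/bond
# predicates).  Supported atom primitives: element symbols (aliphatic),
# lowercase aromatic symbols, #n atomic number, *, A, a, Xn (total
# connections incl. implicit H), Dn (explicit degree), Hn (total hydrogens),
# +n / -n / + / - / +0, R / R0 (ring membership), rn (in ring of size n) and
# ! negation, combined with & (high-and, also implicit), ',' (or) and ';'
# (low-and).  Bonds: default (single-or-aromatic), -, =, #, :, ~.  Branches
# and ring-closure digits as in SMILES.  No recursive SMARTS, no stereo.

ATOMIC_NUMBERS <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11,
                    Mg = 12, P = 15, S = 16, Cl = 17, K = 19, Ca = 20,
                    Fe = 26, Zn = 30, Se = 34, Br = 35, I = 53)

parse_smarts <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  n <- length(chars)
  pos <- 1L
  atoms <- list()     # each: list of or-alternatives; alternative = list of prims
  bonds <- list()     # list(a1, a2, type)
  stack <- integer(0)
  prev <- NA_integer_
  pending <- ""
  ring_open <- list()

  fail <- function(msg) rs_error(
    sprintf("SMARTS parse failure in '%s' at %d: %s", pattern, pos, msg),
    "rs_format_error")

  add_atom <- function(expr) {
    atoms[[length(atoms) + 1]] <<- expr
    length(atoms)
  }
  add_bond <- function(i, j, type) {
    bonds[[length(bonds) + 1]] <<- list(a1 = i, a2 = j,
                                        type = if (nzchar(type)) type else "default")
  }

  parse_bracket <- function(body) {
    # precedence: ';' < ',' < '&'/juxtaposition < '!'
    lapply(strsplit(body, ";", fixed = TRUE)[[1]], function(andpart) {
      lapply(strsplit(andpart, ",", fixed = TRUE)[[1]], function(alt) {
        prims <- list()
        s <- alt
        while (nzchar(s)) {
          if (startsWith(s, "&")) { s <- substr(s, 2, nchar(s)); next }
          neg <- FALSE
          while (startsWith(s, "!")) { neg <- !neg; s <- substr(s, 2, nchar(s)) }
          m <- regmatches(s, regexec(
            "^(#\\d+|\\*|[A-Z][a-z]?|[a-z]|\\+\\d+|-\\d+|\\++|-+|X\\d+|D\\d+|H\\d*|R\\d*|r\\d+)", s))[[1]]
          if (!length(m)) fail(sprintf("bad primitive near '%s'", s))
          prims[[length(prims) + 1]] <- list(tok = m[2], neg = neg)
          s <- substr(s, nchar(m[2]) + 1, nchar(s))
        }
        prims
      })
    })
  }

  while (pos <= n) {
    ch <- chars[pos]
    if (ch == "(") {
      if (is.na(prev)) fail("branch with no atom")
      stack <- c(stack, prev); pos <- pos + 1L
    } else if (ch == ")") {
      if (!length(stack)) fail("unbalanced ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pending <- ch; pos <- pos + 1L
    } else if (grepl("[0-9]", ch)) {
      key <- ch
      if (is.null(ring_open[[key]])) ring_open[[key]] <- list(atom = prev, bond = pending)
      else {
        op <- ring_open[[key]]
        add_bond(op$atom, prev, if (nzchar(pending)) pending else op$bond)
        ring_open[[key]] <- NULL
      }
      pending <- ""; pos <- pos + 1L
    } else if (ch == "[") {
      depth <- 1L; q <- pos + 1L
      while (q <= n && depth > 0) {
        if (chars[q] == "[") depth <- depth + 1L
        if (chars[q] == "]") depth <- depth - 1L
        q <- q + 1L
      }
      if (depth != 0) fail("unbalanced bracket")
      body <- substr(pattern, pos + 1, q - 2)
      cur <- add_atom(parse_bracket(body))
      if (!is.na(prev)) add_bond(prev, cur, pending)
      pending <- ""; prev <- cur; pos <- q
    } else if (grepl("[A-Za-z*]", ch)) {
      two <- if (pos < n) paste0(ch, chars[pos + 1]) else ch
      if (two %in% c("Cl", "Br")) { tok <- two; pos <- pos + 2L }
      else { tok <- ch; pos <- pos + 1L }
      cur <- add_atom(list(list(list(list(tok = tok, neg = FALSE)))))
      if (!is.na(prev)) add_bond(prev, cur, pending)
      pending <- ""; prev <- cur
    } else fail("unexpected character")
  }
  if (length(stack)) fail("unbalanced '(' (unclosed branch)")
  if (length(ring_open)) fail("unclosed ring number")
  if (!length(atoms)) fail("empty pattern")
  list(atoms = atoms, bonds = bonds, n = length(atoms))
}

# Context precomputed once per molecule for predicate evaluation.  Atom and
# bond attributes are held as plain vectors: the backtracking inner loop must
# not pay data.frame row-indexing costs.
smarts_context <- function(mol) {
  adj <- adjacency_list(mol)
  list(mol = mol, adj = adj,
       symbol = mol$atoms$symbol, aromatic = mol$atoms$aromatic,
       charge = mol$atoms$charge, hcount = mol$atoms$hcount,
       degree = lengths(adj),
       in_ring = ring_atom_flags(mol),
       ring_sizes = atom_ring_sizes(mol),
       bond_order = mol$bonds$order, bond_aromatic = mol$bonds$aromatic,
       bmap = bond_index_map(mol))
}

prim_match <- function(ctx, i, prim) {
  tok <- prim$tok
  val <- if (tok == "*") TRUE
  else if (tok == "A") !ctx$aromatic[i]
  else if (tok == "a") ctx$aromatic[i]
  else if (startsWith(tok, "#")) {
    z <- ATOMIC_NUMBERS[[ctx$symbol[i]]] %||% -1
    z == as.integer(substr(tok, 2, 10))
  }
  else if (tok %in% names(ATOMIC_NUMBERS))
    ctx$symbol[i] == tok && !ctx$aromatic[i]
  else if (grepl("^[a-z]$", tok))
    ctx$symbol[i] == toupper(tok) && ctx$aromatic[i]
  else if (startsWith(tok, "X"))
    ctx$degree[i] + ctx$hcount[i] == as.integer(substr(tok, 2, 10))
  else if (startsWith(tok, "D"))
    ctx$degree[i] == as.integer(substr(tok, 2, 10))
  else if (startsWith(tok, "H")) {
    want <- if (tok == "H") 1L else as.integer(substr(tok, 2, 10))
    ctx$hcount[i] == want
  }
  else if (grepl("^\\+\\d+$", tok)) ctx$charge[i] == as.integer(substr(tok, 2, 10))
  else if (grepl("^-\\d+$", tok)) ctx$charge[i] == -as.integer(substr(tok, 2, 10))
  else if (grepl("^\\++$", tok)) ctx$charge[i] == nchar(tok)
  else if (grepl("^-+$", tok)) ctx$charge[i] == -nchar(tok)
  else if (tok == "R") ctx$in_ring[i]
  else if (tok == "R0") !ctx$in_ring[i]
  else if (grepl("^R\\d+$", tok)) ctx$in_ring[i]  # ring-count >= 1 approximation
  else if (grepl("^r\\d+$", tok))
    as.integer(substr(tok, 2, 10)) %in% ctx$ring_sizes[[i]]
  else rs_error(sprintf("unsupported SMARTS primitive '%s'", tok),
                "rs_format_error")
  if (prim$neg) !val else val
}

atom_expr_match <- function(ctx, i, expr) {
  # expr: list over ';' parts, each a list over ',' alternatives,
  # each alternative a list of primitives (AND)
  all(vapply(expr, function(andpart) {
    any(vapply(andpart, function(alt) {
      all(vapply(alt, function(p) prim_match(ctx, i, p), TRUE))
    }, TRUE))
  }, TRUE))
}

bond_expr_match <- function(ctx, i, j, type) {
  k <- ctx$bmap[paste(min(i, j), max(i, j), sep = "-")]
  if (is.na(k)) return(FALSE)
  ord <- ctx$bond_order[k]; arom <- ctx$bond_aromatic[k]
  switch(type,
         "default" = ord == 1 || arom,
         "-" = ord == 1 && !arom,
         "=" = ord == 2 && !arom,
         "#" = ord == 3,
         ":" = arom,
         "~" = TRUE,
         FALSE)
}

#' Match a SMARTS-subset pattern against a molecule
#'
#' @param mol an `rs_mol`.
#' @param pattern SMARTS string (see the package vignette for the supported
#'   subset) or a pre-parsed pattern from `parse_smarts()`.
#' @param all return every match (list of atom-index vectors, pattern order)
#'   instead of a single logical.
#' @return logical, or a list of integer vectors when `all = TRUE`.
#' @export
smarts_match <- function(mol, pattern, all = FALSE) {
  smarts_match_ctx(smarts_context(mol), pattern, all = all)
}

# context-reusing variant: `ctx` from smarts_context(); avoids re-deriving
# ring membership etc. when many patterns are matched against one molecule
smarts_match_ctx <- function(ctx, pattern, all = FALSE) {
  pat <- if (is.character(pattern)) parse_smarts(pattern) else pattern
  mol <- ctx$mol
  n_mol <- n_atoms(mol)
  # pattern adjacency
  padj <- rep(list(integer()), pat$n)
  for (b in pat$bonds) {
    padj[[b$a1]] <- c(padj[[b$a1]], b$a2)
    padj[[b$a2]] <- c(padj[[b$a2]], b$a1)
  }
  pbond <- list()
  for (b in pat$bonds) pbond[[paste(min(b$a1, b$a2), max(b$a1, b$a2), sep = "-")]] <- b$type
  # DFS order over pattern atoms so each new atom (after the first) touches a
  # mapped one
  ord <- integer(0); seen <- logical(pat$n)
  dfs <- function(v) {
    seen[v] <<- TRUE; ord <<- c(ord, v)
    for (w in padj[[v]]) if (!seen[w]) dfs(w)
  }
  dfs(1L)
  if (!all(seen))
    rs_error("disconnected SMARTS patterns are unsupported", "rs_format_error")

  matches <- list()
  assign_vec <- rep(NA_integer_, pat$n)
  found <- FALSE
  bt <- function(step) {
    if (found && !all) return()
    if (step > pat$n) {
      matches[[length(matches) + 1]] <<- assign_vec
      found <<- TRUE
      return()
    }
    pv <- ord[step]
    cands <- if (step == 1) seq_len(n_mol) else {
      anchors <- intersect(padj[[pv]], ord[seq_len(step - 1)])
      av <- assign_vec[anchors[1]]
      ctx$adj[[av]]
    }
    for (mv in cands) {
      if (mv %in% assign_vec) next
      if (!atom_expr_match(ctx, mv, pat$atoms[[pv]])) next
      ok <- TRUE
      for (pw in intersect(padj[[pv]], ord[seq_len(step - 1)])) {
        ty <- pbond[[paste(min(pv, pw), max(pv, pw), sep = "-")]]
        if (!bond_expr_match(ctx, mv, assign_vec[pw], ty)) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_vec[pv] <<- mv
      bt(step + 1)
      assign_vec[pv] <<- NA_integer_
      if (found && !all) return()
    }
  }
  bt(1L)
  if (all) matches else found
}
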