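# Independent oracles used across the suite.  These deliberately do not
# share code paths with the implementation they check.

# Table 2 formulas coded directly from the definitions, with the stated
# identity convention (identical vectors -> 1).
oracle_measure <- function(a, b, c, d, measure) {
  n <- a + b + c + d
  if (b == 0 && c == 0) return(1)
  safe <- function(num, den) if (den == 0) 0 else num / den
  switch(measure,
         tanimoto = safe(a, a + b + c),
         dice = safe(2 * a, 2 * a + b + c),
         ochiai = safe(a, sqrt((a + b) * (a + c))),
         simpson = safe(a, min(a + b, a + c)),
         russell_rao = safe(a, n),
         sokal_michener = safe(a + d, n),
         faith = safe(a + 0.5 * d, n),
         gower_legendre = safe(a + d, a + 0.5 * (b + c) + d),
         rogers_tanimoto = safe(a + d, a + 2 * (b + c) + d),
         stop("oracle: unknown measure"))
}

# Brute-force greedy pairing over a precomputed score matrix: repeatedly
# scan for the maximum free entry (ties: lowest row, then lowest column).
oracle_greedy <- function(S) {
  pairs <- NULL
  freeA <- rep(TRUE, nrow(S)); freeB <- rep(TRUE, ncol(S))
  while (any(freeA) && any(freeB)) {
    best <- -Inf; bi <- NA; bj <- NA
    for (i in seq_len(nrow(S))) for (j in seq_len(ncol(S))) {
      if (freeA[i] && freeB[j] && S[i, j] > best + 1e-15) {
        best <- S[i, j]; bi <- i; bj <- j
      }
    }
    pairs <- rbind(pairs, c(bi, bj, best))
    freeA[bi] <- FALSE; freeB[bj] <- FALSE
  }
  pairs
}

# Independent reaction-center oracle: dense map-by-map bond-order matrices
# per side (aromatic = 1.5); center = maps whose incident-order row differs,
# plus mapped atoms whose hydrogen count changes.
oracle_center <- function(rxn) {
  maps <- sort(unique(unlist(lapply(c(rxn$substrates, rxn$products),
                                    function(m) m$atoms$map))))
  maps <- maps[maps > 0]
  side_matrix <- function(mols) {
    M <- matrix(0, length(maps), length(maps), dimnames = list(maps, maps))
    H <- setNames(rep(NA_real_, length(maps)), maps)
    for (m in mols) {
      for (i in seq_len(nrow(m$atoms)))
        if (m$atoms$map[i] > 0)
          H[as.character(m$atoms$map[i])] <- m$atoms$hcount[i]
      if (nrow(m$bonds)) for (q in seq_len(nrow(m$bonds))) {
        m1 <- as.character(m$atoms$map[m$bonds$a1[q]])
        m2 <- as.character(m$atoms$map[m$bonds$a2[q]])
        if (m1 == "0" || m2 == "0") next
        ov <- if (m$bonds$aromatic[q]) 1.5 else m$bonds$order[q]
        M[m1, m2] <- ov; M[m2, m1] <- ov
      }
    }
    list(M = M, H = H)
  }
  S <- side_matrix(rxn$substrates); P <- side_matrix(rxn$products)
  ctr <- maps[rowSums(S$M != P$M) > 0]
  hctr <- maps[!is.na(S$H) & !is.na(P$H) & S$H != P$H]
  sort(unique(c(ctr, hctr)))
}

# Mann-Whitney AUC oracle (rank-based)
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# mock fingerprint built directly from a set-bit index vector
mock_fp <- function(on, n = 20L, type = "extended") {
  bits <- logical(n); bits[on] <- TRUE
  structure(list(bits = bits, length = n, fp_type = type), class = "rs_fp")
}

# small shared fixture set (cached per test run)
fixture_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_fixtures(seed = 42, n_per_family = 3)
    cache
  }
})
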