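# Whole-reaction-level similarity: greedily pair molecules across the two
# reactions side-wise (substrates with substrates, products with products),
# maximizing the selected measure at each pick; the reaction score is the
# unweighted mean of the pair scores over both sides; unpaired molecules are
# dropped.

#' Greedy molecule pairing by fingerprint similarity
#'
#' Iteratively selects the globally highest-scoring unpaired (i, j) pair,
#' records it and removes both molecules, until one side is exhausted.  Ties
#' are broken towards the lower index in A, then the lower index in B, so
#' batch runs are reproducible.  Greedy pairing is deliberately not the
#' optimal assignment.
#'
#' @param fpsA,fpsB lists of `rs_fp` (same type and length).
#' @param measure similarity measure name.
#' @return list with `pairs` (data.frame `i`, `j`, `score`, in pick order,
#'   scores non-increasing), `unpaired_A`, `unpaired_B`.
#' @export
greedy_pair <- function(fpsA, fpsB, measure = "tanimoto") {
  nA <- length(fpsA); nB <- length(fpsB)
  pairs <- data.frame(i = integer(), j = integer(), score = numeric())
  if (nA && nB) {
    S <- matrix(0, nA, nB)
    for (i in seq_len(nA)) for (j in seq_len(nB))
      S[i, j] <- similarity(bit_counts(fpsA[[i]], fpsB[[j]]), measure)
    freeA <- rep(TRUE, nA); freeB <- rep(TRUE, nB)
    while (any(freeA) && any(freeB)) {
      best <- -Inf; bi <- 0L; bj <- 0L
      for (i in which(freeA)) for (j in which(freeB)) {
        if (S[i, j] > best + 1e-15) { best <- S[i, j]; bi <- i; bj <- j }
      }
      pairs[nrow(pairs) + 1, ] <- list(bi, bj, best)
      freeA[bi] <- FALSE; freeB[bj] <- FALSE
    }
    unpaired_A <- which(freeA); unpaired_B <- which(freeB)
  } else {
    unpaired_A <- seq_len(nA); unpaired_B <- seq_len(nB)
  }
  list(pairs = pairs, unpaired_A = unpaired_A, unpaired_B = unpaired_B)
}

# pair one side of two reactions; returns pairing plus the molecules involved
pair_side <- function(molsA, molsB, fp_type, measure, fp_length = NULL) {
  fpsA <- lapply(molsA, fingerprint, fp_type = fp_type, length = fp_length)
  fpsB <- lapply(molsB, fingerprint, fp_type = fp_type, length = fp_length)
  greedy_pair(fpsA, fpsB, measure)
}

#' Whole-reaction-level similarity
#'
#' Pairs substrates of A against substrates of B and products of A against
#' products of B by [greedy_pair()]; the score is the unweighted mean of the
#' pair scores over all pairs from both sides combined.  With
#' `orientation = "auto"` reaction B is additionally evaluated reversed and
#' the larger score is returned (off by default; sides are never crossed
#' within one orientation).
#'
#' @param rxnA,rxnB `rs_reaction` objects.
#' @param fp_type fingerprint type.
#' @param measure similarity measure.
#' @param orientation `"forward"` or `"auto"`.
#' @param detail return the pairing trace alongside the score.
#' @return the score in `[0, 1]`, or (with `detail = TRUE`) a list with
#'   `score`, `substrate_pairing`, `product_pairing`, `orientation`.
#' @export
reaction_similarity <- function(rxnA, rxnB, fp_type = "extended",
                                measure = "tanimoto",
                                orientation = c("forward", "auto"),
                                detail = FALSE) {
  orientation <- match.arg(orientation)
  eval_fwd <- function(B) {
    ps <- pair_side(rxnA$substrates, B$substrates, fp_type, measure)
    pp <- pair_side(rxnA$products, B$products, fp_type, measure)
    scores <- c(ps$pairs$score, pp$pairs$score)
    list(score = if (length(scores)) mean(scores) else 0,
         substrate_pairing = ps, product_pairing = pp)
  }
  res <- eval_fwd(rxnB)
  used <- "forward"
  if (orientation == "auto") {
    rev_rxn <- rxnB
    rev_rxn$substrates <- rxnB$products
    rev_rxn$products <- rxnB$substrates
    res_rev <- eval_fwd(rev_rxn)
    if (res_rev$score > res$score) { res <- res_rev; used <- "reversed" }
  }
  if (detail) c(res, list(orientation = used)) else res$score
}
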