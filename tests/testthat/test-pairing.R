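test_that("greedy_pair identity, cardinality and empty-side behaviour", {
  fps <- lapply(list(1:3, 4:6, c(1, 7, 9)), mock_fp)
  res <- greedy_pair(fps, fps)
  expect_equal(res$pairs$i, 1:3)
  expect_equal(res$pairs$j, 1:3)
  expect_equal(res$pairs$score, rep(1, 3))
  expect_length(res$unpaired_A, 0)

  res <- greedy_pair(fps, fps[1])
  expect_equal(nrow(res$pairs), 1)
  expect_length(res$unpaired_A, 2)

  res <- greedy_pair(list(), fps)
  expect_equal(nrow(res$pairs), 0)
  expect_equal(res$unpaired_B, 1:3)
})

test_that("greedy picks the global maximum first even when suboptimal overall", {
  # russell_rao on length-20 mocks gives an exact score matrix
  # [[0.9, 0.2], [0.85, 0.1]]: greedy takes (1,1)=0.9 then (2,2)=0.1,
  # mean 0.5; the optimal assignment (1,2)+(2,1) would average 0.525
  A <- list(mock_fp(1:19), mock_fp(c(1:16, 19, 20)))
  B <- list(mock_fp(c(1:18, 20)), mock_fp(c(1, 2, 17, 18)))
  S <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    S[i, j] <- similarity(bit_counts(A[[i]], B[[j]]), "russell_rao")
  expect_equal(S, matrix(c(0.9, 0.85, 0.2, 0.1), 2, 2))

  res <- greedy_pair(A, B, "russell_rao")
  expect_equal(res$pairs$i, c(1, 2))
  expect_equal(res$pairs$j, c(1, 2))
  expect_equal(res$pairs$score, c(0.9, 0.1))
  expect_equal(mean(res$pairs$score), 0.5)
  expect_gt(mean(c(S[1, 2], S[2, 1])), mean(res$pairs$score))
  # pick-order scores are non-increasing
  expect_true(all(diff(res$pairs$score) <= 0))
})

test_that("greedy trace equals the independent brute-force greedy on fixtures", {
  fx <- fixture_set()
  rxns <- fx$reactions[c(1, 2, 4, 5, 7, 10)]
  for (qa in seq_along(rxns)) for (qb in seq_along(rxns)) {
    if (qa >= qb) next
    for (side in c("substrates", "products")) {
      fpsA <- lapply(rxns[[qa]][[side]], fingerprint, fp_type = "circular")
      fpsB <- lapply(rxns[[qb]][[side]], fingerprint, fp_type = "circular")
      S <- matrix(0, length(fpsA), length(fpsB))
      for (i in seq_along(fpsA)) for (j in seq_along(fpsB))
        S[i, j] <- similarity(bit_counts(fpsA[[i]], fpsB[[j]]), "tanimoto")
      expected <- oracle_greedy(S)
      got <- greedy_pair(fpsA, fpsB, "tanimoto")
      expect_equal(got$pairs$i, expected[, 1])
      expect_equal(got$pairs$j, expected[, 2])
      expect_equal(got$pairs$score, expected[, 3])
    }
  }
})

test_that("reaction_similarity: self-similarity, disjoint and unpaired molecules", {
  r <- parse_reaction("CC(=O)OC.O>>CC(=O)O.CO")
  for (t in fingerprint_types())
    expect_equal(reaction_similarity(r, r, fp_type = t), 1)

  # entirely disjoint bit sets score 0 under tanimoto
  r1 <- parse_reaction("CCCC>>CCCC")
  r2 <- parse_reaction("O=S(=O)(O)O>>O=S(=O)(O)O")
  expect_equal(reaction_similarity(r1, r2), 0)

  # unpaired molecule is dropped: A = X.Y>>Z vs B = X>>Z scores 1
  A <- parse_reaction("CCO.N>>CC=O")
  B <- parse_reaction("CCO>>CC=O")
  det <- reaction_similarity(A, B, detail = TRUE)
  expect_equal(det$score, 1)
  expect_equal(nrow(det$substrate_pairing$pairs), 1)
  expect_equal(det$substrate_pairing$unpaired_A, 2)

  # removing an unpaired molecule never changes the score
  expect_equal(reaction_similarity(A, B), reaction_similarity(B, B))
})

test_that("orientation auto restores symmetry for reversed databases", {
  fwd <- parse_reaction("CC(=O)OC.O>>CC(=O)O.CO")
  rev <- parse_reaction("CC(=O)O.CO>>CC(=O)OC.O")
  expect_lt(reaction_similarity(fwd, rev), 1)
  expect_equal(reaction_similarity(fwd, rev, orientation = "auto"), 1)
  # score symmetry under swap with auto orientation
  fx <- fixture_set()
  for (q in list(c(1, 5), c(2, 9), c(4, 11))) {
    a <- fx$reactions[[q[1]]]; b <- fx$reactions[[q[2]]]
    expect_equal(reaction_similarity(a, b, orientation = "auto"),
                 reaction_similarity(b, a, orientation = "auto"))
  }
})

test_that("reaction scores stay within [0, 1] across measures on fixtures", {
  fx <- fixture_set()
  a <- fx$reactions[[1]]; b <- fx$reactions[[8]]
  for (m in measure_names()) {
    s <- reaction_similarity(a, b, measure = m)
    expect_true(s >= 0 && s <= 1, info = m)
  }
})
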