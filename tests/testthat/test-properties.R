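test_that("molecular mass sums standard atomic weights with implicit H", {
  expect_equal(molecular_mass(parse_molecule("O")), 18.015, tolerance = 1e-3)
  expect_equal(molecular_mass(parse_molecule("C")), 16.043, tolerance = 1e-3)
  # map annotations never change the mass
  expect_equal(molecular_mass(parse_molecule("[CH3:1][OH:2]")),
               molecular_mass(parse_molecule("CO")))
})

test_that("additive volume reproduces published anchors and is monotone", {
  # published VABC anchor values: benzene 81.2, cyclohexane 99.9 (A^3)
  expect_equal(molecular_volume(parse_molecule("c1ccccc1")), 81.2,
               tolerance = 0.01)
  expect_equal(molecular_volume(parse_molecule("C1CCCCC1")), 99.9,
               tolerance = 0.01)
  expect_lt(molecular_volume(parse_molecule("c1ccccc1")),
            molecular_volume(parse_molecule("C1CCCCC1")))
  v <- vapply(c("C", "CC", "CCC", "CCCC"),
              function(s) molecular_volume(parse_molecule(s)), numeric(1))
  expect_true(all(diff(v) > 0))
  # atom input order invariance
  expect_equal(molecular_volume(parse_molecule("CC(=O)O")),
               molecular_volume(parse_molecule("OC(C)=O")))
})

test_that("protonation states follow the majority rule at the given pH", {
  # acetic acid (pKa 4.8): carboxylate at pH 7, neutral at pH 3
  ac7 <- assign_charges_at_pH(parse_molecule("CC(=O)O"), 7)
  expect_equal(sum(ac7$atoms$charge), -1)
  ac3 <- assign_charges_at_pH(parse_molecule("CC(=O)O"), 3)
  expect_equal(sum(ac3$atoms$charge), 0)

  # methylamine (pKa 10.6): ammonium at pH 7, neutral at pH 12
  ma7 <- assign_charges_at_pH(parse_molecule("CN"), 7)
  expect_equal(sum(ma7$atoms$charge), 1)
  ma12 <- assign_charges_at_pH(parse_molecule("CN"), 12)
  expect_equal(sum(ma12$atoms$charge), 0)

  # ethanol: no ionizable group at any pH
  for (ph in c(0, 7, 14))
    expect_equal(sum(assign_charges_at_pH(parse_molecule("CCO"), ph)$atoms$charge), 0)

  # glycine at pH 7 is a zwitterion; assignment is idempotent
  gly <- assign_charges_at_pH(parse_molecule("NCC(=O)O"), 7)
  expect_equal(sum(gly$atoms$charge), 0)
  expect_equal(sort(gly$atoms$charge), c(-1, 0, 0, 0, 1))
  expect_identical(assign_charges_at_pH(gly, 7)$atoms, gly$atoms)

  expect_error(assign_charges_at_pH(parse_molecule("C"), 15),
               class = "rs_config_error")
})

test_that("pH-adjusted charges feed the enhanced fingerprint", {
  neutral <- enhanced_fingerprint(parse_molecule("CC(=O)O"))
  charged <- enhanced_fingerprint(assign_charges_at_pH(parse_molecule("CC(=O)O"), 7))
  expect_false(identical(neutral$bits, charged$bits))
})

test_that("Jaccard similarity, distance and the Rs correction obey Eqs. on a grid", {
  expect_equal(jaccard_similarity(18.015, 18.015), 1)
  expect_equal(jaccard_similarity(50, 100), 0.5)
  expect_equal(jaccard_similarity(100, 50), 0.5)
  expect_error(jaccard_similarity(-1, 5), class = "rs_validation_error")

  expect_equal(jaccard_distance(list(rbind(c(10, 10), c(50, 100)))), 0.25)
  expect_equal(jaccard_distance(list(rbind(c(3, 3)))), 0)
  # both properties selected: mean of per-property distances
  expect_equal(jaccard_distance(list(rbind(c(50, 100)), rbind(c(10, 10)))), 0.25)
  expect_error(jaccard_distance(list(matrix(numeric(0), 0, 2))),
               class = "rs_correction_error")

  expect_equal(corrected_similarity(0.8, 0), 0.8)
  expect_equal(corrected_similarity(0.8, 1), 0.4)
  # hand grid: Rs = Rf/(1+Jdist), and Rf/2 <= Rs <= Rf
  for (Rf in seq(0, 1, by = 0.1)) for (Jd in seq(0, 1, by = 0.1)) {
    Rs <- corrected_similarity(Rf, Jd)
    expect_equal(Rs, Rf / (1 + Jd))
    expect_true(Rs >= Rf / 2 - 1e-12 && Rs <= Rf + 1e-12)
  }
  expect_error(corrected_similarity(1.2, 0), class = "rs_validation_error")
})

test_that("end-to-end correction: Rs <= Rf with equality iff equal properties", {
  fx <- fixture_set()
  for (q in list(c(1, 2), c(1, 4), c(4, 7), c(7, 10), c(2, 11))) {
    res <- corrected_reaction_similarity(fx$reactions[[q[1]]],
                                         fx$reactions[[q[2]]])
    expect_lte(res$Rs, res$Rf + 1e-12)
    expect_equal(res$Rs, res$Rf / (1 + res$Jdist))
  }
  # identical reactions: all paired properties equal, Jdist 0, Rs == Rf
  res <- corrected_reaction_similarity(fx$reactions[[1]], fx$reactions[[1]])
  expect_equal(res$Jdist, 0)
  expect_equal(res$Rs, res$Rf)
  expect_equal(res$Rf, 1)
})

test_that("transformation-level correction works behind the same flag", {
  fx <- fixture_set()
  res <- corrected_reaction_similarity(fx$reactions[[1]], fx$reactions[[2]],
                                       level = "transformation", k = 1)
  expect_true(res$Rs <= res$Rf + 1e-12)
  expect_true(res$N >= 1)
})
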