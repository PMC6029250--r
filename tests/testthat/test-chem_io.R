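bond_mult <- function(m) {
  if (!nrow(m$bonds)) return(character(0))
  vapply(seq_len(nrow(m$bonds)), function(k) {
    ends <- sort(m$atoms$symbol[c(m$bonds$a1[k], m$bonds$a2[k])])
    paste(ends[1], ends[2], if (m$bonds$aromatic[k]) "ar" else m$bonds$order[k])
  }, "")
}

n_atoms_of <- function(m) nrow(m$atoms)

test_that("parse_molecule handles the basic SMILES contract", {
  m <- parse_molecule("O")
  expect_equal(nrow(m$atoms), 1)
  expect_equal(nrow(m$bonds), 0)
  expect_equal(m$atoms$hcount, 2)

  m <- parse_molecule("[CH3:1][OH:2]")
  expect_equal(nrow(m$atoms), 2)
  expect_equal(nrow(m$bonds), 1)
  expect_setequal(m$atoms$map, c(1, 2))
  expect_equal(m$atoms$symbol, c("C", "O"))

  expect_error(parse_molecule("C("), class = "rs_format_error")
  expect_error(parse_molecule("C1CC"), class = "rs_format_error")
  expect_error(parse_molecule("[CH3:1][CH3:1]"), class = "rs_mapping_error")
  expect_error(parse_molecule("CC.O"), class = "rs_format_error")
})

test_that("serialization round-trips preserve the attributed graph", {
  cases <- c("CCO", "c1ccccc1", "C1=CC=CC=C1", "CC(=O)[O-]",
             "C[C@@H](N)C(=O)O", "C[C@H](N)C(=O)O", "F/C=C/F", "F/C=C\\F",
             "[CH3:1][C:2](=[O:3])[O:4][CH3:5]", "C1CCCCC1",
             "c1ccc2ccccc2c1", "OC(=O)CCC(=O)O", "[NH3+]CC([O-])=O",
             "O=P(O)(O)OC", "c1cc[nH]c1")
  for (s in cases) {
    m <- parse_molecule(s)
    s2 <- serialize_molecule(m)
    m2 <- parse_molecule(s2)
    # isomorphism check through invariant multisets plus a second
    # serialization pass (canonical form is a fixed point)
    expect_identical(serialize_molecule(m2), s2, info = s)
    expect_identical(sort(m$atoms$symbol), sort(m2$atoms$symbol), info = s)
    expect_identical(sort(m$atoms$charge), sort(m2$atoms$charge), info = s)
    expect_identical(sort(m$atoms$hcount), sort(m2$atoms$hcount), info = s)
    expect_identical(sort(m$atoms$map), sort(m2$atoms$map), info = s)
    expect_identical(sort(m$atoms$stereo), sort(m2$atoms$stereo), info = s)
    expect_equal(nrow(m$bonds), nrow(m2$bonds), info = s)
    expect_identical(sort(bond_mult(m)), sort(bond_mult(m2)), info = s)
  }
})

test_that("kekule benzene and aromatic benzene fingerprint identically", {
  a <- parse_molecule("c1ccccc1")
  b <- parse_molecule("C1=CC=CC=C1")
  expect_identical(serialize_molecule(a), serialize_molecule(b))
})

test_that("parse_reaction computes side structure and the mapped flag", {
  r <- parse_reaction("CCO.O>>CC(=O)O")
  expect_length(r$substrates, 2)
  expect_length(r$products, 1)
  expect_false(r$mapped)

  r <- parse_reaction("[CH3:1][OH:2]>>[CH3:1][OH:2]")
  expect_true(r$mapped)

  # partially mapped: unmapped oxygen breaks the mapped invariant
  r <- parse_reaction("[CH3:1]O>>[CH3:1]O")
  expect_false(r$mapped)

  # side order is preserved
  r <- parse_reaction("O.CC>>CCO")
  expect_equal(n_atoms_of(r$substrates[[1]]), 1)
  expect_equal(n_atoms_of(r$substrates[[2]]), 2)

  expect_error(parse_reaction(">>CC"), class = "rs_validation_error")
  expect_error(parse_reaction("CC>>"), class = "rs_validation_error")
  expect_error(parse_reaction("[CH3:1][CH3:1]>>CC"), class = "rs_mapping_error")
  expect_error(parse_reaction("[CH3:1]C.[CH4:1]>>CC.C"), class = "rs_mapping_error")
})

test_that("RXN V2000 round-trip preserves molecules, maps and charges", {
  r <- parse_reaction("[CH3:1][C:2](=[O:3])[O:4][CH3:5].[OH2:6]>>[CH3:1][C:2](=[O:3])[OH:6].[OH:4][CH3:5]")
  path <- withr::local_tempfile(fileext = ".rxn")
  write_rxn(r, path)
  r2 <- parse_reaction(paste(readLines(path), collapse = "\n"))
  expect_length(r2$substrates, 2)
  expect_length(r2$products, 2)
  expect_true(r2$mapped)
  expect_identical(serialize_reaction(r2), serialize_reaction(r))

  rq <- parse_reaction("[NH3+:1]C>>[NH3+:1]C")
  path2 <- withr::local_tempfile(fileext = ".rxn")
  write_rxn(rq, path2)
  rq2 <- parse_reaction(paste(readLines(path2), collapse = "\n"))
  expect_equal(rq2$substrates[[1]]$atoms$charge[
    rq2$substrates[[1]]$atoms$map == 1], 1)
})

test_that("read_reaction_table reads, labels and skips per strictness", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\treaction\tec",
               "r1\tCCO>>CC=O\t1.1.1.1",
               "r2\tbroken(((\t2.6.1.1",
               "r3\tCC(=O)OC.O>>CC(=O)O.CO\t3.1.1.1"), path)
  expect_warning(rxns <- read_reaction_table(path), "row 2")
  expect_length(rxns, 2)
  expect_equal(rxns[[1]]$id, "r1")
  expect_equal(rxns[[2]]$ec, "3.1.1.1")
  expect_error(read_reaction_table(path, strict = TRUE), class = "rs_format_error")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tsmiles", "r1\tCCO>>CC=O"), bad)
  expect_error(read_reaction_table(bad), class = "rs_config_error")
})
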