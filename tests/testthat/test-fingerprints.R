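test_that("circular fingerprint: single-atom collapse, determinism, map invariance", {
  fp <- circular_fingerprint(parse_molecule("C"))
  expect_s3_class(fp, "rs_fp")
  expect_equal(fp$length, 1024)
  expect_equal(sum(fp$bits), 1)   # radius 0 and 1 collapse for lone atoms

  m <- parse_molecule("CC(=O)NC")
  expect_identical(circular_fingerprint(m)$bits, circular_fingerprint(m)$bits)

  plain <- circular_fingerprint(parse_molecule("CCO"))
  mapped <- circular_fingerprint(parse_molecule("[CH3:7][CH2:2][OH:9]"))
  expect_identical(plain$bits, mapped$bits)
})

test_that("fingerprints are invariant to atom input order", {
  variants <- list(
    c("CC(=O)O", "OC(C)=O", "C(C)(=O)O"),
    c("c1ccccc1O", "Oc1ccccc1"),
    c("NCC(=O)O", "OC(=O)CN", "C(N)C(O)=O"))
  for (grp in variants) {
    ref <- lapply(FP_SET <- c("circular", "extended", "substructure", "enhanced"),
                  function(t) fingerprint(parse_molecule(grp[1]), t))
    for (alt in grp[-1]) {
      for (q in seq_along(FP_SET)) {
        expect_identical(fingerprint(parse_molecule(alt), FP_SET[q])$bits,
                         ref[[q]]$bits, info = paste(alt, FP_SET[q]))
      }
    }
  }
})

test_that("extended fingerprint separates ring systems from chains", {
  benzene <- extended_fingerprint(parse_molecule("c1ccccc1"))
  cyclohexane <- extended_fingerprint(parse_molecule("C1CCCCC1"))
  hexane <- extended_fingerprint(parse_molecule("CCCCCC"))
  expect_equal(benzene$length, 1024)
  expect_false(identical(benzene$bits, cyclohexane$bits))
  expect_false(identical(hexane$bits, cyclohexane$bits))
})

test_that("substructure fingerprint uses the 307-key set", {
  keys <- substructure_keys()
  expect_length(keys, 307)
  expect_false(anyDuplicated(keys) > 0)

  fp <- substructure_fingerprint(parse_molecule("CC(=O)O"))
  expect_equal(fp$length, 307)
  # the carboxyl key bit is set for a carboxylic acid
  expect_true(fp$bits[which(keys == "[CX3](=O)[OX2H1]")])
  # independent check of that one key with a direct matcher call
  expect_true(smarts_match(parse_molecule("CC(=O)O"), "[CX3](=O)[OX2H1]"))
  expect_false(smarts_match(parse_molecule("CCO"), "[CX3](=O)[OX2H1]"))

  # a bare noble-ish molecule with no functional groups still has carbon keys,
  # but water matches no carbon-centred keys beyond the element patterns
  expect_true(sum(substructure_fingerprint(parse_molecule("O"))$bits) <
                sum(fp$bits))
  expect_error(substructure_keys("no/such/file.smarts"),
               class = "rs_config_error")
})

test_that("enhanced fingerprint is stereo- and charge-sensitive, base block intact", {
  L <- parse_molecule("C[C@@H](N)C(=O)O")
  D <- parse_molecule("C[C@H](N)C(=O)O")
  expect_false(identical(enhanced_fingerprint(L)$bits, enhanced_fingerprint(D)$bits))
  expect_identical(extended_fingerprint(L)$bits, extended_fingerprint(D)$bits)

  acid <- parse_molecule("CC(=O)O")
  anion <- parse_molecule("CC(=O)[O-]")
  ea <- enhanced_fingerprint(acid); eb <- enhanced_fingerprint(anion)
  expect_false(identical(ea$bits, eb$bits))
  expect_equal(ea$length, 1024 + 64)

  # achiral neutral molecule: extension block all zero, base == extended
  neutral <- enhanced_fingerprint(parse_molecule("CCO"))
  expect_equal(sum(neutral$bits[1025:1088]), 0)
  expect_identical(neutral$bits[1:1024],
                   extended_fingerprint(parse_molecule("CCO"))$bits)

  # E/Z isomers differ in the extension block
  eE <- enhanced_fingerprint(parse_molecule("F/C=C/F"))
  eZ <- enhanced_fingerprint(parse_molecule("F/C=C\\F"))
  expect_false(identical(eE$bits, eZ$bits))
})

test_that("stereo sensitivity is representation-independent", {
  # the same enantiomer written from different starting atoms must hash to
  # the same parity signature
  a <- enhanced_fingerprint(parse_molecule("C[C@@H](N)C(=O)O"))
  b <- enhanced_fingerprint(parse_molecule("N[C@H](C)C(=O)O"))
  expect_identical(a$bits, b$bits)
})

test_that("self-similarity is 1 for every fingerprint type and measure", {
  mols <- lapply(c("CC(=O)OC", "NCC(=O)O", "c1ccccc1O"), parse_molecule)
  for (t in fingerprint_types()) {
    for (mol in mols) {
      fp <- fingerprint(mol, t)
      ct <- bit_counts(fp, fp)
      for (m in measure_names()) expect_equal(similarity(ct, m), 1)
    }
  }
})

test_that("fingerprint() validates the type name", {
  expect_error(fingerprint(parse_molecule("C"), "morgan"), class = "rs_enum_error")
})
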