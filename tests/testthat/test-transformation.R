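# manually derived reaction-center annotations for the fixture templates
# (bond-set differences worked out by hand from the template SMILES)
TEMPLATE_CENTERS <- list(
  ester_hydrolysis = c(1, 3, 4),       # C1-O3 broken, C1-O4 formed
  transamination = c(1, 2, 6, 7),      # C-N and C=O swap between skeletons
  phosphoryl_transfer = c(25, 26, 30), # P26-O25 broken, P26-O30 formed
  dehydrogenation = c(1, 2))           # C1-O2 order 1 -> 2

ESTER <- "[CH3:1][C:2](=[O:3])[O:4][CH3:5].[OH2:6]>>[CH3:1][C:2](=[O:3])[OH:6].[OH:4][CH3:5]"

test_that("find_reaction_center matches hand-derived bond-set differences", {
  r <- parse_reaction(ESTER)
  expect_equal(find_reaction_center(r), c(2, 4, 6))

  # identity reaction: empty center
  expect_equal(find_reaction_center(parse_reaction("[CH3:1][OH:2]>>[CH3:1][OH:2]")),
               integer(0))

  # bond-order change places both atoms in the center
  expect_equal(find_reaction_center(parse_reaction("[CH2:1]=[CH2:2]>>[CH3:1][CH3:2]")),
               c(1, 2))

  # unmapped input is refused with guidance
  expect_error(find_reaction_center(parse_reaction("CCO>>CC=O")),
               class = "rs_mapping_error")

  # every fixture family reproduces its annotated template center
  fx <- fixture_set()
  for (r in fx$reactions) {
    fam <- sub("_\\d+$", "", r$id)
    expect_equal(find_reaction_center(r), TEMPLATE_CENTERS[[fam]], info = r$id)
  }
})

test_that("center detection equals the independent matrix-differ oracle", {
  fx <- fixture_set()
  extra <- list(parse_reaction(ESTER),
                parse_reaction("[CH2:1]=[CH2:2].[OH2:3]>>[CH3:1][CH2:2][OH:3]"))
  for (r in c(fx$reactions, extra)) {
    expect_equal(find_reaction_center(r), oracle_center(r),
                 info = r$id %||% "extra")
  }
})

test_that("center detection is invariant under consistent map renumbering", {
  r1 <- parse_reaction(ESTER)
  # same reaction with every single-digit map m relabelled to m + 10
  shifted <- gsub(":([0-9])\\]", ":1\\1]", ESTER)
  r2 <- parse_reaction(shifted)
  expect_equal(find_reaction_center(r2), find_reaction_center(r1) + 10)
})

test_that("transformation regions: induced fragments and degree monotonicity", {
  r <- parse_reaction(ESTER)
  reg0 <- extract_transformation_region(r, 0)
  expect_equal(reg0$center_atoms, c(2, 4, 6))
  # k = 0: fragments induced on exactly the center atoms
  maps_of <- function(frags) sort(unlist(lapply(frags, function(m) m$atoms$map)))
  expect_equal(maps_of(reg0$substrate_fragments), c(2, 4, 6))
  expect_equal(maps_of(reg0$product_fragments), c(2, 4, 6))

  # saturation: large k reaches the whole molecules
  regBig <- extract_transformation_region(r, 10)
  expect_equal(maps_of(regBig$substrate_fragments), 1:6)

  # monotone region growth in k, on every fixture
  fx <- fixture_set()
  for (r in fx$reactions[seq(1, 12, by = 3)]) {
    sizes <- vapply(0:3, function(k) {
      reg <- extract_transformation_region(r, k)
      length(unlist(lapply(c(reg$substrate_fragments, reg$product_fragments),
                           function(m) m$atoms$map)))
    }, numeric(1))
    expect_true(all(diff(sizes) >= 0), info = r$id)
  }

  # empty-center region carries a warning and no fragments
  expect_warning(
    reg <- extract_transformation_region(
      parse_reaction("[CH3:1][OH:2]>>[CH3:1][OH:2]"), 1),
    class = "reactsim_warning")
  expect_length(reg$substrate_fragments, 0)
})

test_that("cut-bond valences are completed with implicit hydrogens", {
  r <- parse_reaction(ESTER)
  reg0 <- extract_transformation_region(r, 0)
  # the acyl carbon (map 2) lost C1 and =O3: its k=0 fragment carbon gains 3 H
  frag_c <- NULL
  for (f in reg0$substrate_fragments)
    if (2 %in% f$atoms$map) frag_c <- f
  expect_equal(frag_c$atoms$hcount[frag_c$atoms$map == 2], 3)
})

test_that("transformation similarity: self, family discrimination", {
  r <- parse_reaction(ESTER)
  for (k in 0:2)
    expect_equal(transformation_similarity(r, r, k), 1)

  # two hydrolyses of different esters: identical centers at k = 0
  r2 <- parse_reaction("[CH3:11][CH2:1][C:2](=[O:3])[O:4][CH2:5][CH3:12].[OH2:6]>>[CH3:11][CH2:1][C:2](=[O:3])[OH:6].[OH:4][CH2:5][CH3:12]")
  s_hydro_k0 <- transformation_similarity(r, r2, 0)
  expect_equal(s_hydro_k0, 1)
  # whole-reaction score is lower than the k = 0 transformation score
  expect_lt(reaction_similarity(r, r2), s_hydro_k0)

  # a hydrolysis vs a transamination scores strictly below two hydrolyses
  fx <- fixture_set()
  trans <- Filter(function(x) grepl("transamination", x$id), fx$reactions)[[1]]
  expect_lt(transformation_similarity(r, trans, 1),
            transformation_similarity(r, r2, 1))
})
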