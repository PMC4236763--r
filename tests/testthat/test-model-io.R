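test_that("JSON models read back with file order and validation", {
  td <- withr::local_tempdir()
  paths <- write_fixture_models(td)

  toy <- read_network(paths[["toy_synthetic"]])
  expect_equal(length(toy$metabolite_ids), 8L)
  expect_equal(length(toy$reaction_ids), 14L)
  expect_identical(toy$reaction_ids[1:3], c("R01", "R02", "R03"))

  chain <- read_network(paths[["chain"]], format = "json")
  expect_equal(dim(chain$stoich), c(2L, 3L))

  # write -> read round trip preserves the matrix exactly
  rt <- read_network(paths[["diamond"]])
  expect_equal(unname(rt$stoich), unname(fixture_diamond()$stoich))
})

test_that("TSV equation dialect parses, flags externals and rejects junk", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("up\tx_glc -> A\tI",
               "conv\tA -> 2 B\tR",
               "dn\t2 B ->\tI"), tf)
  net <- read_network(tf)
  expect_equal(net$metabolite_ids, c("A", "B"))      # x_glc excluded
  expect_equal(unname(net$stoich[, "conv"]), c(-1, 2))
  expect_true(net$reversible[2])

  writeLines(c("r1\tA -> B\tI", "r1\tB ->\tI"), tf)
  expect_error(read_network(tf), "duplicate reaction id")

  writeLines("r1\tq A -> B\tI", tf)
  expect_error(read_network(tf), "malformed coefficient")

  writeLines("r1\tA + B\tI", tf)
  expect_error(read_network(tf), "->")
})

test_that("SBML level-3 import maps boundary species to externals", {
  sf <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfSpecies>',
    '<species id="A" boundaryCondition="false"/>',
    '<species id="Xext" boundaryCondition="true"/>',
    '</listOfSpecies><listOfReactions>',
    '<reaction id="up" reversible="false"><listOfReactants>',
    '<speciesReference species="Xext" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A"/></listOfProducts></reaction>',
    '<reaction id="dn" reversible="true"><listOfReactants>',
    '<speciesReference species="A" stoichiometry="1"/></listOfReactants></reaction>',
    '</listOfReactions></model></sbml>'), sf)
  net <- read_network(sf, format = "sbml")
  expect_equal(net$metabolite_ids, "A")
  expect_equal(unname(net$stoich["A", ]), c(1, -1))
  expect_identical(net$reversible, c(FALSE, TRUE))
})

test_that("network validation rejects bad input", {
  expect_error(
    metabolic_network(cbind(c(1, 0), c(0, 0)), c("a", "b"), c("M1", "M2")),
    "all-zero")
  expect_warning(
    net <- metabolic_network(cbind(c(1, 0), c(0, 0)), c("a", "b"),
                             c("M1", "M2"), drop_zero_columns = TRUE),
    "dropping")
  expect_equal(net$reaction_ids, "a")
  expect_error(
    metabolic_network(cbind(c(1, 0)), "a", c("M1", "M1")),
    "duplicate metabolite")
  expect_error(
    metabolic_network(cbind(c(NA, 0)), "a", c("M1", "M2")),
    "finite")
})

test_that("reversible splitting doubles columns and merges back exactly", {
  net <- metabolic_network(cbind(c(1, 0), c(-1, 1), c(0, -1)),
                           c("r1", "r2", "r3"), c("A", "B"),
                           reversible = c(FALSE, TRUE, FALSE))
  sp <- split_reversible(net)
  expect_false(any(sp$reversible))
  expect_equal(length(sp$reaction_ids), 4L)
  sm <- attr(sp, "split_map")
  expect_named(sm, "r2")
  fwd <- sp$stoich[, sm$r2[1]]
  bwd <- sp$stoich[, sm$r2[2]]
  expect_equal(bwd, -fwd)
  expect_equal(unname(fwd), unname(net$stoich[, "r2"]))

  # identity case
  irr <- split_reversible(fixture_chain())
  expect_identical(irr$stoich, fixture_chain()$stoich)
  expect_length(attr(irr, "split_map"), 0L)

  # id collisions are refused
  clash <- metabolic_network(cbind(c(1, 0), c(-1, 1), c(1, -1)),
                             c("r1", "r2", "r2_rev"), c("A", "B"),
                             reversible = c(FALSE, TRUE, FALSE))
  expect_error(split_reversible(clash), "collision")
})

test_that("reaction permutation is seeded and EFM-invariant", {
  di <- fixture_diamond()
  expect_identical(permute_reactions(di, seed = 0L)$stoich, di$stoich)
  p1 <- permute_reactions(di, seed = 7L)
  p2 <- permute_reactions(di, seed = 7L)
  expect_identical(p1$stoich, p2$stoich)

  perm <- attr(p1, "perm")
  o <- brute_force_efms(di)
  op <- brute_force_efms(p1)
  relabeled <- efm_set(efm_supports(o)[, perm, drop = FALSE] * 1,
                       p1$reaction_ids)
  expect_same_modes(op, relabeled)
})
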