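test_that("a linear chain lumps to a single exchange-to-exchange reaction", {
  res <- compress_network(fixture_chain())
  expect_equal(length(res$network$reaction_ids), 1L)
  expect_equal(nrow(res$network$stoich), 0L)
  g <- res$map$groups[[1]]
  expect_equal(g$kind, "subset")
  ids <- vapply(g$members, `[[`, "", "id")
  ratios <- vapply(g$members, `[[`, 1, "ratio")
  expect_setequal(ids, c("r1", "r2", "r3"))
  expect_equal(unname(ratios), c(1, 1, 1), tolerance = 1e-9)
})

test_that("duplicate columns merge only when asked, recording the group", {
  S <- cbind(c(1, 0), c(-1, 1), c(-2, 2), c(0, -1))
  net <- metabolic_network(S, c("up", "a1", "a2", "dn"), c("A", "B"))
  off <- compress_network(net, lump_subsets = FALSE)
  expect_equal(length(off$network$reaction_ids), 4L)

  on <- compress_network(net, lump_subsets = FALSE, merge_duplicates = TRUE)
  expect_equal(length(on$network$reaction_ids), 3L)
  dup <- Filter(function(g) g$kind == "duplicate", on$map$groups)
  expect_length(dup, 1L)
  expect_equal(dup[[1]]$id, "a1")
})

test_that("blocked reactions are dropped; infeasible networks empty out", {
  # r3 produces C which nothing consumes: r3 is blocked
  S <- cbind(c(1, 0, 0), c(-1, 1, 0), c(-1, 0, 1), c(0, -1, 0))
  net <- metabolic_network(S, c("r1", "r2", "r3", "r4"), c("A", "B", "C"))
  res <- compress_network(net, lump_subsets = FALSE)
  expect_true("r3" %in% res$map$dropped)
  expect_false("r3" %in% res$network$reaction_ids)

  # dead-end only: every reaction blocked
  S2 <- cbind(c(1, 0), c(-1, 1))
  net2 <- metabolic_network(S2, c("r1", "r2"), c("A", "B"))
  res2 <- compress_network(net2)
  expect_length(res2$network$reaction_ids, 0L)
  expect_setequal(res2$map$dropped, c("r1", "r2"))
})

test_that("compression preserves the EFM set one-to-one under expansion", {
  nets <- list(chain = fixture_chain(), diamond = fixture_diamond(),
               toy = fixture_toy())
  for (seed in 1:20) {
    net <- oracle_scale_network(seed)
    if (!is.null(net)) nets[[paste0("rand", seed)]] <- net
  }
  for (nm in names(nets)) {
    net <- nets[[nm]]
    o <- brute_force_efms(net)
    res <- compress_network(net)
    comp <- if (length(res$network$reaction_ids)) {
      enumerate_efms(res$network)
    } else efm_set(matrix(0, 0, 0), character(0))
    expect_equal(length(comp), length(o), label = nm)
    back <- expand_efms(comp, res$map, net$reaction_ids)
    expect_same_modes(back, o)
  }
})

test_that("expansion validates dimensions and identity maps are no-ops", {
  di <- fixture_diamond()
  res <- compress_network(di, lump_subsets = FALSE)   # identity here
  e <- enumerate_efms(di)
  back <- expand_efms(e, res$map, di$reaction_ids)
  expect_equal(unname(back$fluxes), unname(e$fluxes))
  wrong <- efm_set(matrix(1, 1, 2), c("x", "y"))
  expect_error(expand_efms(wrong, res$map, di$reaction_ids), "groups")
})

test_that("FVA reduction keeps optimal-yield routes and is idempotent", {
  di <- fixture_diamond()
  expect_setequal(fva_reduce(di, "r6", "r1")$reaction_ids, di$reaction_ids)

  lossy <- lossy_diamond()
  red <- fva_reduce(lossy, "r6", "r1")
  expect_setequal(red$reaction_ids, c("r1", "r2", "r4", "r6"))
  red2 <- fva_reduce(red, "r6", "r1")
  expect_identical(red2$reaction_ids, red$reaction_ids)
  # column subset of the input
  expect_true(all(red$reaction_ids %in% lossy$reaction_ids))

  # a network whose objective is reachable one way keeps that pathway only
  chainy <- metabolic_network(
    cbind(c(1, 0), c(-1, 1), c(0, -1), c(-1, 0)),
    c("up", "conv", "dn", "waste"), c("A", "B"))
  red3 <- fva_reduce(chainy, "dn", "up")
  expect_setequal(red3$reaction_ids, c("up", "conv", "dn"))

  # an objective that can never carry flux is refused
  dead <- metabolic_network(
    cbind(c(1, 0, 0), c(-1, 1, 0), c(0, -1, 0), c(0, 0, -1)),
    c("r1", "r2", "r3", "wasteC"), c("A", "B", "C"))
  expect_error(fva_reduce(dead, "wasteC", "r1"), "zero|infeasible")
})

test_that("drain replacement decomposes a composite equation", {
  bio <- metabolic_network(
    cbind(c(1, 0, 0), c(0, 1, 0), c(-1, -2, 1), c(0, 0, -1)),
    c("upX", "upY", "biomass", "dnZ"), c("X", "Y", "Z"))
  out <- replace_with_drains(bio, "biomass")
  expect_false("biomass" %in% out$reaction_ids)
  expect_true(all(c("drain_X", "drain_Y", "source_Z") %in% out$reaction_ids))
  expect_equal(unname(out$stoich[, "drain_X"]), c(-1, 0, 0))
  expect_equal(unname(out$stoich[, "source_Z"]), c(0, 0, 1))
  expect_error(replace_with_drains(bio, "nothere"), "unknown reaction")
  expect_error(replace_with_drains(bio, "upX"), "consumes no")
})
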