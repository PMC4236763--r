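test_that("fixture networks enumerate to their known mode counts", {
  expect_length(enumerate_efms(fixture_chain()), 1L)
  expect_length(enumerate_efms(fixture_diamond()), 2L)
  expect_length(enumerate_efms(fixture_toy()), 9L)
  expect_equal(unname(as.matrix(enumerate_efms(fixture_chain()))[1, ]),
               c(1, 1, 1))
})

test_that("an infeasible constraint set yields an empty stream, not an error", {
  di <- fixture_diamond()
  out <- enumerate_efms(di, constraint_set(iff = c(2, 3), faf = 6))
  expect_length(out, 0L)
  # dof-0 networks have no modes
  one <- metabolic_network(cbind(c(1, -1)), "r1", c("A", "B"))
  expect_length(enumerate_efms(one), 0L)
})

test_that("emitted identification sets are distinct, leading and independent", {
  for (net in list(fixture_toy(), fixture_diamond())) {
    b <- nullspace_basis(net$stoich)
    res <- enumerate_efms(net, basis = b)
    ids <- attr(res, "iff_sets")
    keys <- vapply(ids, paste, "", collapse = ",")
    expect_false(anyDuplicated(keys) > 0)
    sup <- efm_supports(res)
    for (i in seq_along(ids)) {
      expect_length(ids[[i]], b$dof - 1L)
      expect_equal(rank_of(b$ns[ids[[i]], , drop = FALSE]), b$dof - 1L)
      # the identification is the leading independent subset of the
      # mode's inactive reactions
      inact <- which(!sup[i, ])
      expect_true(all(ids[[i]] %in% inact))
      greedy <- integer(0)
      for (j in inact) {
        if (length(greedy) == b$dof - 1L) break
        if (rank_of(b$ns[c(greedy, j), , drop = FALSE]) ==
            length(greedy) + 1L) greedy <- c(greedy, j)
      }
      expect_identical(ids[[i]], greedy)
    }
  }
})

test_that("every emitted mode is elementary regardless of search path", {
  for (seed in c(1, 6, 14, 22)) {
    net <- oracle_scale_network(seed)
    if (is.null(net)) next
    res <- enumerate_efms(net)
    sup <- efm_supports(res)
    for (i in seq_len(nrow(sup))) {
      expect_true(is_elementary(sup[i, ], net$stoich))
    }
  }
})

test_that("flux-bound constrained enumeration equals post-filtering", {
  di <- fixture_diamond()
  con <- enumerate_efms(di, constraint_set(
    flux_bounds = cbind(reaction = 4, k = 1)))
  expect_length(con, 1L)
  expect_true(efm_supports(con)[1, 4])

  for (seed in c(2, 8, 13, 17, 25)) {
    net <- oracle_scale_network(seed)
    if (is.null(net)) next
    full <- enumerate_efms(net)
    if (!length(full)) next
    sup <- efm_supports(full)
    r <- ((seed * 5) %% ncol(sup)) + 1L
    k <- 0.5 + (seed %% 3)
    con <- enumerate_efms(net, constraint_set(
      flux_bounds = cbind(reaction = r, k = k)))
    keep <- support_keys(full)[sup[, r]]
    expect_setequal(support_keys(con), keep)
  }
})

test_that("enumeration results do not depend on the LP backend", {
  for (net in list(fixture_diamond(), fixture_toy())) {
    expect_same_modes(enumerate_efms(net, backend = "simplex"),
                      enumerate_efms(net, backend = "quadprog"))
  }
})

test_that("retained records never exceed the batch size", {
  net <- ladder_network(6)                   # 64 modes
  flushed <- 0L
  res <- enumerate_efms(net, batch_size = 5L,
                        sink = function(b, s) flushed <<- flushed + nrow(b))
  ctr <- attr(res, "counters")
  expect_gte(ctr$n_efms, 10L * 5L)
  expect_lte(ctr$peak_buffer, 5L)
  expect_equal(flushed + nrow(res$fluxes), ctr$n_efms)
})

test_that("a snapshot taken at any flush resumes to the identical set", {
  toy <- fixture_toy()
  full <- enumerate_efms(toy)
  states <- list()
  batches <- list()
  enumerate_efms(toy, batch_size = 2L, sink = function(b, s) {
    batches[[length(batches) + 1L]] <<- b
    states[[length(states) + 1L]] <<- s
  })
  expect_gte(length(states), 3L)
  for (k in seq_along(states)) {
    resumed <- enumerate_efms(toy, resume_state = states[[k]])
    got <- efm_set(rbind(do.call(rbind, batches[seq_len(k)]),
                         resumed$fluxes), toy$reaction_ids)
    expect_equal(length(unique(support_keys(got))), nrow(got$fluxes))
    expect_same_modes(got, full)
  }
})
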